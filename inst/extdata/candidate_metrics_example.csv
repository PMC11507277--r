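model,accuracy,precision,recall,f1,kappa
xgboost,0.9215,0.9139,0.9102,0.9070,0.8972
rf,0.9126,0.9083,0.8926,0.9003,0.8810
elm,0.8931,0.8849,0.8961,0.8904,0.8721
tabnet,0.9108,0.8920,0.9056,0.8987,0.8891
svm,0.9079,0.8949,0.9097,0.9022,0.8862
dndt,0.9115,0.9013,0.9171,0.9091,0.8846
mlp,0.8907,0.8724,0.8965,0.8843,0.8693
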