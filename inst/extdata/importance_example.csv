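model,p1,p2,p3,p4,p_max,p_min,p_mean,p_std
xgboost,0.1713,0.1924,0.2671,0.2567,0.0186,0.0745,0.0086,0.0107
svm,0.1998,0.2463,0.1181,0.0511,0.0374,0.1997,0.1139,0.0336
dndt,0.2556,0.2434,0.1791,0.0873,0.0242,0.0839,0.0718,0.0498
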