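model,f1,kappa,accuracy
lightgbm,0.9139,0.9020,0.9266
adaboost,0.8977,0.8791,0.9054
bagging,0.9012,0.8864,0.9049
hard_voting,0.9059,0.8802,0.9103
soft_voting,0.9142,0.8933,0.9201
stacking,0.9362,0.9235,0.9448
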