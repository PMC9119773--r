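stage,model,accuracy,sensitivity,specificity,kappa,auc,rmse
learner,ANN,82.61,0.791,0.848,0.653,0.883,0.365
learner,Linear SVM,80.65,0.813,0.800,0.613,0.881,0.372
learner,RBF SVM,79.80,0.813,0.783,0.595,0.870,0.379
learner,Random forest,79.30,0.830,0.757,0.587,0.857,0.411
learner,LR,80.00,0.817,0.783,0.600,0.873,0.380
risk_score,ANN-RS,81.000,0.826,0.791,0.620,0.876,0.378
risk_score,SVM-RS,83.500,0.826,0.843,0.670,0.888,0.362
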