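model,brier,spiegelhalter_z,spiegelhalter_p,h_statistic,h_p,auc
ANN-RS,0.142,-1.791,0.073,13.719,0.089,0.876
SVM-RS,0.115,-1.443,0.150,14.427,0.071,0.888
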