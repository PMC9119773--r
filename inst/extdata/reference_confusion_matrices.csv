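stage,model,tp,fn,fp,tn
learner,ANN,185,45,35,195
learner,Linear SVM,187,43,46,184
learner,RBF SVM,187,43,50,180
learner,Random forest,191,39,56,174
learner,LR,188,42,50,180
risk_score,ANN-RS,190,40,48,182
risk_score,SVM-RS,190,40,36,194
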