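feature,label,ann_raw,ann_relative,svm_raw,svm_relative
age_groups,Age groups,0.836,11.944,1.085,8.828
parental_history,Parental history of CVDs,0.401,5.735,0.330,2.683
general_stress,Self-reported general stress,0.360,5.138,0.732,5.957
high_salty_food,Consumption of high salty foods,0.429,6.128,1.024,8.338
low_fruit,Low fruit consumption,0.666,9.517,0.832,6.773
physical_inactivity,Physical inactivity,0.562,8.024,1.167,9.499
fried_trans_fats,High fried foods/trans fats,0.404,5.770,0.857,6.976
abdominal_obesity,Abdominal obesity,0.406,5.794,1.046,8.512
diabetes,Diabetes mellitus,0.446,6.371,0.978,7.961
hypertension,Hypertension,0.737,10.527,1.386,11.283
smoking_history,Smoking history,0.635,9.067,0.969,7.887
low_vegetables,Low vegetables consumption,0.588,8.394,0.894,7.273
red_meat,Red meat/poultry consumption,0.531,7.591,0.987,8.030
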