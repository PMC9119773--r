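subject,age_groups,parental_history,general_stress,high_salty_food,low_fruit,physical_inactivity,fried_trans_fats,abdominal_obesity,diabetes,hypertension,smoking_history,low_vegetables,red_meat
worked_example,0,0,0,1,0,1,0,0,1,1,1,0,0
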