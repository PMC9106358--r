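item,criterion,threshold,hallmark
y1,larger_longer,4,persistence
y2,larger_longer,5,persistence
y3,larger_longer,4,persistence
y4,unsuccessful_cutdown,4,persistence
y5,unsuccessful_cutdown,5,persistence
y6,unsuccessful_cutdown,4,persistence
y7,time_spent,4,motivation
y8,time_spent,5,motivation
y9,time_spent,4,motivation
y10,craving,4,persistence
y11,craving,5,persistence
y12,craving,4,persistence
y13,activities_given_up,4,motivation
y14,activities_given_up,5,motivation
y15,activities_given_up,4,motivation
y16,use_despite_problems,4,compulsion
y17,use_despite_problems,5,compulsion
y18,use_despite_problems,4,compulsion
y19,failure_role_obligations,4,other
y20,failure_role_obligations,5,other
y21,failure_role_obligations,4,other
y22,interpersonal_problems,4,other
y23,interpersonal_problems,5,other
y24,interpersonal_problems,4,other
y25,hazardous_use,4,compulsion
y26,hazardous_use,5,compulsion
y27,hazardous_use,4,compulsion
y28,tolerance,4,motivation
y29,tolerance,5,motivation
y30,tolerance,4,motivation
y31,withdrawal,4,compulsion
y32,withdrawal,5,compulsion
y33,withdrawal,4,compulsion
y34,clinical_significance,4,other
y35,clinical_significance,4,other
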