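dataset,model,tp,fn,tn,fp,auc,sensitivity,specificity,balanced_accuracy
validation,connectedness,12,178,1966,18,NA,0.063,0.991,0.527
validation,ccr,90,100,1958,26,NA,0.474,0.987,0.730
validation,zscore,130,60,1793,191,0.852,0.684,0.904,0.794
validation,md,154,36,1671,313,0.899,0.811,0.842,0.826
validation,ae,145,45,1812,172,0.896,0.763,0.913,0.838
validation,zscore_combined,155,35,1818,166,NA,0.816,0.916,0.866
validation,md_combined,160,30,1828,156,NA,0.842,0.921,0.882
validation,ae_combined,164,26,1797,187,NA,0.863,0.906,0.884
test,connectedness,2,35,1984,21,NA,0.054,0.990,0.522
test,ccr,17,20,1969,36,NA,0.459,0.982,0.721
test,zscore,27,10,1811,194,0.922,0.730,0.903,0.816
test,md,32,5,1679,326,0.939,0.865,0.837,0.851
test,ae,31,6,1791,214,0.939,0.838,0.893,0.866
test,zscore_combined,31,6,1848,157,NA,0.838,0.922,0.880
test,md_combined,33,4,1819,186,NA,0.892,0.907,0.900
test,ae_combined,32,5,1779,226,NA,0.865,0.887,0.876
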