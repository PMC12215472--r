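approach,metric,run_id,value
fixed_weight_ensemble,accuracy_standard,1,97.34
fixed_weight_ensemble,accuracy_standard,2,96.11
fixed_weight_ensemble,accuracy_standard,3,96.96
fixed_weight_ensemble,accuracy_standard,4,96.57
fixed_weight_ensemble,accuracy_standard,5,96.29
fixed_weight_ensemble,f1_standard,1,97.11
fixed_weight_ensemble,f1_standard,2,96.19
fixed_weight_ensemble,f1_standard,3,96.92
fixed_weight_ensemble,f1_standard,4,96.57
fixed_weight_ensemble,f1_standard,5,96.36
fixed_weight_ensemble,accuracy_occluded,1,94.71
fixed_weight_ensemble,accuracy_occluded,2,94.67
fixed_weight_ensemble,accuracy_occluded,3,94.56
fixed_weight_ensemble,accuracy_occluded,4,93.51
fixed_weight_ensemble,accuracy_occluded,5,93.48
fixed_weight_ensemble,f1_occluded,1,94.40
fixed_weight_ensemble,f1_occluded,2,94.19
fixed_weight_ensemble,f1_occluded,3,94.02
fixed_weight_ensemble,f1_occluded,4,93.49
fixed_weight_ensemble,f1_occluded,5,93.34
fuzzy_ensemble,accuracy_standard,1,98.19
fuzzy_ensemble,accuracy_standard,2,98.01
fuzzy_ensemble,accuracy_standard,3,97.51
fuzzy_ensemble,accuracy_standard,4,97.33
fuzzy_ensemble,accuracy_standard,5,97.24
fuzzy_ensemble,f1_standard,1,98.21
fuzzy_ensemble,f1_standard,2,98.01
fuzzy_ensemble,f1_standard,3,97.59
fuzzy_ensemble,f1_standard,4,97.21
fuzzy_ensemble,f1_standard,5,97.09
fuzzy_ensemble,accuracy_occluded,1,95.47
fuzzy_ensemble,accuracy_occluded,2,94.97
fuzzy_ensemble,accuracy_occluded,3,94.61
fuzzy_ensemble,accuracy_occluded,4,94.58
fuzzy_ensemble,accuracy_occluded,5,94.21
fuzzy_ensemble,f1_occluded,1,95.08
fuzzy_ensemble,f1_occluded,2,94.26
fuzzy_ensemble,f1_occluded,3,94.22
fuzzy_ensemble,f1_occluded,4,94.13
fuzzy_ensemble,f1_occluded,5,94.12
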