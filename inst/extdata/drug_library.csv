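name,ic50_na_M,ic50_cal_M,ic50_kr_M,ic50_ks_M,ik1_block_pct,concentration_M,known_group,provenance
dofetilide,,,1e-08,,0,1.4e-07,A1,literature-derived approximation; synthetic configuration value
sotalol,,,1e-04,,0,1e-04,A1,literature-derived approximation; synthetic configuration value
terfenadine,1e-06,1e-06,5.6e-08,,0,3e-07,A2,literature-derived approximation; synthetic configuration value
thioridazine,3e-06,1.4e-06,5e-07,,10,1e-06,A2,literature-derived approximation; synthetic configuration value
quinidine,1.6e-05,1.5e-05,7e-07,4e-05,20,3e-06,A2,literature-derived approximation; synthetic configuration value
moxifloxacin,,,1e-04,,0,1e-05,B,literature-derived approximation; synthetic configuration value
verapamil,,2e-07,1.4e-07,,0,1e-07,B,literature-derived approximation; synthetic configuration value
risperidone,,,3e-07,,0,6e-08,B,literature-derived approximation; synthetic configuration value
phenytoin,5e-05,,,,0,2e-05,C,literature-derived approximation; synthetic configuration value
propranolol,2e-06,,3e-06,,0,1e-06,C,literature-derived approximation; synthetic configuration value
nicardipine,,1e-07,1e-06,,0,1e-07,C,literature-derived approximation; synthetic configuration value
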