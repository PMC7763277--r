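quantity	value
families_total	42
affected_individuals	66
healthy_relatives	113
total_individuals	179
patients_sequenced	46
ps_tested_families	42
ces_tested_families	11
wes_tested_families	5
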