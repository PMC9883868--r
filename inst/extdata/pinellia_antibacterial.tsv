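sample_id	organism	mic_ug_ml	izd_mm	izd_sd_mm
compound_1	S_aureus	>100	NI	NA
compound_1	M_tetragenus	>100	NI	NA
compound_1	E_coli	>100	NI	NA
compound_1	P_syringae	>100	NI	NA
compound_2	S_aureus	>100	NI	NA
compound_2	M_tetragenus	>100	NI	NA
compound_2	E_coli	>100	NI	NA
compound_2	P_syringae	>100	15.3	0.6
compound_3	S_aureus	>100	14.2	0.5
compound_3	M_tetragenus	>100	NI	NA
compound_3	E_coli	>100	NI	NA
compound_3	P_syringae	>100	NI	NA
compound_4	S_aureus	100	13.3	0.2
compound_4	M_tetragenus	>100	NI	NA
compound_4	E_coli	>100	NI	NA
compound_4	P_syringae	25	16.2	0.6
compound_5	S_aureus	1.56	33.7	0.5
compound_5	M_tetragenus	3.13	31.0	0.8
compound_5	E_coli	1.56	36.0	0.8
compound_5	P_syringae	1.56	40.2	0.7
compound_6	S_aureus	>100	NI	NA
compound_6	M_tetragenus	>100	NI	NA
compound_6	E_coli	>100	NI	NA
compound_6	P_syringae	>100	NI	NA
compound_7	S_aureus	100	10.0	0.7
compound_7	M_tetragenus	>100	NI	NA
compound_7	E_coli	>100	NI	NA
compound_7	P_syringae	6.25	26.0	0.5
gentamicin_sulfate	S_aureus	1.56	21.7	0.6
gentamicin_sulfate	M_tetragenus	3.13	25.7	0.9
gentamicin_sulfate	E_coli	3.13	26.7	0.5
gentamicin_sulfate	P_syringae	6.25	26.0	1.0
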