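plant	tissue	index	value
P_ternata	root	S	5
P_ternata	root	D_margalef	2.7906
P_ternata	root	H_shannon	1.5607
P_ternata	root	D_simpson	0.7778
P_ternata	root	PIE	0.9333
P_ternata	root	lambda_dominance	0.2222
P_ternata	root	J_pielou	0.9697
P_ternata	stem	S	7
P_ternata	stem	D_margalef	2.5022
P_ternata	stem	H_shannon	1.8938
P_ternata	stem	D_simpson	0.8430
P_ternata	stem	PIE	0.9273
P_ternata	stem	lambda_dominance	0.1570
P_ternata	stem	J_pielou	0.9732
P_ternata	leaf	S	4
P_ternata	leaf	D_margalef	1.4427
P_ternata	leaf	H_shannon	1.2555
P_ternata	leaf	D_simpson	0.6875
P_ternata	leaf	PIE	0.7857
P_ternata	leaf	lambda_dominance	0.3125
P_ternata	leaf	J_pielou	0.9056
P_ternata	tuber	S	12
P_ternata	tuber	D_margalef	3.3011
P_ternata	tuber	H_shannon	2.2299
P_ternata	tuber	D_simpson	0.8673
P_ternata	tuber	PIE	0.8995
P_ternata	tuber	lambda_dominance	0.1327
P_ternata	tuber	J_pielou	0.8974
P_pedatisecta	root	S	4
P_pedatisecta	root	D_margalef	2.1640
P_pedatisecta	root	H_shannon	1.3863
P_pedatisecta	root	D_simpson	0.7500
P_pedatisecta	root	PIE	1.0000
P_pedatisecta	root	lambda_dominance	0.2500
P_pedatisecta	root	J_pielou	1.0000
P_pedatisecta	stem	S	4
P_pedatisecta	stem	D_margalef	1.6743
P_pedatisecta	stem	H_shannon	1.2425
P_pedatisecta	stem	D_simpson	0.6667
P_pedatisecta	stem	PIE	0.8000
P_pedatisecta	stem	lambda_dominance	0.3333
P_pedatisecta	stem	J_pielou	0.8962
P_pedatisecta	leaf	S	6
P_pedatisecta	leaf	D_margalef	2.4045
P_pedatisecta	leaf	H_shannon	1.7329
P_pedatisecta	leaf	D_simpson	0.8125
P_pedatisecta	leaf	PIE	0.9286
P_pedatisecta	leaf	lambda_dominance	0.1875
P_pedatisecta	leaf	J_pielou	0.9671
P_pedatisecta	tuber	S	5
P_pedatisecta	tuber	D_margalef	2.2324
P_pedatisecta	tuber	H_shannon	1.5607
P_pedatisecta	tuber	D_simpson	0.7778
P_pedatisecta	tuber	PIE	0.9333
P_pedatisecta	tuber	lambda_dominance	0.2222
P_pedatisecta	tuber	J_pielou	0.9697
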