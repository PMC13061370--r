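group	category	count
total	births	3394739
total	male	1778746
total	female	1615993
total	gestational_hypertension	103443
term_lbw	births	30145
term_lbw	gestational_hypertension	4915
term_sga	births	113382
term_sga	sample	3394049
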