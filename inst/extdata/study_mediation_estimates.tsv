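variant	outcome	te	direct	indirect	pm_pct
four_step	term_lbw	1.042	1.034	1.008	19.94
four_step	term_sga	1.034	1.029	1.005	13.41
counterfactual_no_interaction	term_lbw	1.055	1.034	1.021	38.82
counterfactual_no_interaction	term_sga	1.037	1.029	1.007	19.96
counterfactual_interaction	term_lbw	1.055	1.035	1.019	35.15
counterfactual_interaction	term_sga	1.036	1.029	1.007	18.82
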