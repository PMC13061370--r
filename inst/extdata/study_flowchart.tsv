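stage	n
eligible_pool	5720445
incomplete_linkage_or_address	2130147
unmarried	125465
missing_o3_exposure	70066
implausible_birth_weight	28
final_analytic_sample	3394739
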