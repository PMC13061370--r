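quantity	value
o3_mean	113.90
o3_sd	13.03
o3_min	62.35
o3_max	157.58
o3_median	112.70
o3_q25	103.60
o3_q75	123.53
o3_iqr	19.93
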