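domain	min_score
GAG	61
AP	55
RT	68
RH	56
INT	62
CHROMO	54
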