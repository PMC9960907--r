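name	max_ca_distance
DSS	30
BS3	30
DSBU	30
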