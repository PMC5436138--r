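replicate_id	induced_channel	labeling_scheme
r1	heavy	silac
r2	light	silac
r3	heavy	silac
r4	light	silac
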