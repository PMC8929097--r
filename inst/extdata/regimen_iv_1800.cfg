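route = "iv_infusion"
dose = 1800            # mg
infusion_duration = 0.5 # h
sim_duration = 24
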