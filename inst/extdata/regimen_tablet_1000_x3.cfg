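route = "oral_tablet_ir"
dose = 1000       # mg
interval = 8      # h
n_doses = 3
dose_volume = 250 # mL
sim_duration = 24
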