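# Gemcitabine drug parameter configuration (key = value)
name = "gemcitabine"
molecular_weight = 263.2        # g/mol
logp = -1.32
solubility = 5.01               # mg/mL
solubility_ph = 7.92
mean_precipitation_time = 900   # s
particle_density = 1.2          # g/mL
particle_radius = 25            # um
diffusion_coefficient = 0.93e-5 # cm2/s
blood_plasma_ratio = 1.12
peff_jejunal = 0.59e-4          # cm/s
fup = 0.846
vc_per_kg = 1.45                # L/kg
clearance = 120                 # L/h
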