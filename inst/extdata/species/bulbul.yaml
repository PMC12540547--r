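# Dark-capped bulbul (~40 g) endotherm parameters.
# Morphometrics and evaporative limits are SYNTHETIC PLACEHOLDERS in the
# realistic range for a 40-g passerine; substitute measured values where
# available. basal_met_W falls back to the 0.029 * mass^0.72 allometry if
# removed.
name: dark-capped bulbul
mass_g: 40
Tb_norm_C: 40.4
Tb_max_C: 46
plumage_depth_m: 0.005
plumage_conductivity_Wm1K1: 0.035
shortwave_absorptance: 0.85
emissivity: 0.95
body_density_kgm3: 1000
shape_elongation: 1.8
baseline_ewl_W: 0.15
max_ewl_W: 1.8
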