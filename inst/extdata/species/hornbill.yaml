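# Southern yellow-billed hornbill (~200 g) endotherm parameters.
# Morphometrics and evaporative limits are SYNTHETIC PLACEHOLDERS in the
# realistic range for a 200-g heat-adapted non-passerine; substitute
# measured values where available.
# - basal_met_W is set explicitly: non-passerines sit well below the
#   passerine metabolic allometry used as the package default.
# - plumage_conductivity is an EFFECTIVE coat value, raised to fold in dry
#   heat loss through the bare bill and facial skin (the hornbill bill is
#   a known radiator).
# - shortwave_absorptance reflects the pale grey-and-white plumage.
name: southern yellow-billed hornbill
mass_g: 200
Tb_norm_C: 39.9
Tb_max_C: 46
basal_met_W: 0.85
plumage_depth_m: 0.007
plumage_conductivity_Wm1K1: 0.055
shortwave_absorptance: 0.70
emissivity: 0.95
body_density_kgm3: 1000
shape_elongation: 2.0
baseline_ewl_W: 0.30
max_ewl_W: 5.5
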