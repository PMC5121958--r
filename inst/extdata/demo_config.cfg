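# Demo configuration for the bundled toy scenario (see ?pipeline_config).
# Paths are omitted, so the model and growth curve are simulated.
seed = 1
n_amino_acids = 6
n_phases = 12
noise_sd = 0
tolerance_activity = 1e-9
tolerance_change = 1e-6
fva_fraction = 1
moma_norm = L2
covariation_threshold = 0.7
scale = none
parsimonious = FALSE
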