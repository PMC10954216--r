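# Example synthetic-assemblage configuration for `ridescore simulate`.
# The nonrider trait prevalences below are ILLUSTRATIVE ONLY: no nonrider
# base rates have been published for any of the six traits, so every
# specificity figure computed from this file is conditional on these rates.
n_individuals: 217
rider_fraction: 0.15
p_trait_rider: [0.9, 0.6, 0.8, 0.7, 0.7, 0.4]
p_trait_nonrider: [0.30, 0.05, 0.20, 0.15, 0.25, 0.10]
preservation: completeness
completeness_range: [20, 95]
sex_male_fraction: 0.61
subadult_fraction: 0.281
seed: 20230303
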