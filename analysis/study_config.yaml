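# Configuration for the scaled-down exhaustive subset study (stage 3).
# The 8-trait mini population keeps the 238-fit enumeration cheap while
# preserving the structure under study: a planted high-saturation trait, a
# planted low-saturation trait, and a floor-effect scale.
data: scratch/data/mini_responses.csv
scale_map: results/subset_study/scale_map.csv
out_dir: results/subset_study
k_min: 2
k_max: 6
seed: 20260930
workers: 2
named_sets:
  triad_like: [strong2, mid2, lowsat]
  tetrad_like: [strong2, mid2, lowsat, floorish]
  triad_swap: [strong2, mid2, mid3]
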