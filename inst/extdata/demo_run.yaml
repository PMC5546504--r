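# Demo pipeline configuration: small fields so a full run finishes in
# about a minute. Keys mirror the arguments of run_config() and the
# stage *_config() constructors; the global seed overrides stage seeds.
seed: 1
alpha_level: 0.05
image:
  image_width_px: 384
  image_height_px: 384
  n_slices: 5
  n_fields: 7
  nuclei_per_field: 4
survival:
  doses_Gy: [0, 2, 4, 6]
  replicates: 3
blot:
  cv: 0.15
  replicates: 4
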