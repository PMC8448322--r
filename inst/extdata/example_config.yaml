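# Example end-to-end run configuration (desk scale).
seed: 1
n_iterations: 2
simulate:
  n_chroms: 2
  chrom_len: 150000
  n_promoters: 30
  n_enhancers: 10
  grammar:
    background_gc: 0.41
model:
  n_res_blocks: 3
  channels: [8, 16, 32]
  kernel: 9
  pool: [8, 4, 2]
  window_len: 1001
train:
  max_epochs: 15
  patience: 3
  neg_ratio: 2
scan:
  stride: 50
  scan_threshold: 0.5
  pred_threshold: 0.5
  min_separation: 500
  window_len: 1001
split:
  test_chroms: [chr1]
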