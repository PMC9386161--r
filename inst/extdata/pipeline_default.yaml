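# Default configuration for the end-to-end pipeline (run_pipeline /
# `heartvox.R pipeline`). Triples are (z, y, x).
phantom:
  volume_shape_vox: [96, 128, 128]
  voxel_size_um: [1.0, 0.32, 0.32]
  noise_sd: 380
strips:
  strip_width_px: 56
  overlap_px: 20
  jitter_px: 2
stitch:
  policy: cut
  search_radius_px: 10
  row_radius_px: 3
pyramid:
  chunk_shape_vox: [32, 32, 32]
  factors: [2, 2, 2]
  method: mean
  max_coarse_vox: 64
render:
  depth_slices: 32
  depth_order: last_hit
vasc:
  min_component_vox: 27
  smoothing_iterations: 10
  curvature_kind: mean
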