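# Demonstration pipeline configuration: simulate a tiny cohort in a
# 2-um constriction and run the full measurement chain.
geometry:
  channel_width_um: 7
  channel_height_um: 5
  constriction_width_um: 2
  constriction_length_um: 15
  constriction_center_x_um: 50
  pixel_size_um: 0.325
  migration_direction: 1
simulate:
  n_cells: 3
  n_frames: 60
  seed: 101
condition: demo_2um
output:
  dir: demo_out
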