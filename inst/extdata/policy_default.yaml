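# Default rule-check policy. All thresholds are institution-tunable;
# none is a published standard. Units are stated per key.
slice_thickness_max_mm:
  SRS: 1.25
  SBRT: 1.25
  IMRT_VMAT: 3.0
  THREE_D: 3.0
  SIMPLE_2D: 3.0
  ELECTRON: 3.0
hu_high_z_threshold: 2000       # HU above which density-override review is required
iso_target_offset_max_mm: 50    # advisory limit on isocenter-to-target-centroid distance
mono_iso_tol_mm: 0.1            # max pairwise isocenter spread for mono-isocenter plans
srs_jaw_mlc_gap_mm: [0, 5]      # allowed jaw-to-leaf-tip gap band for SRS fields
hotspot_threshold_fraction: 1.10  # fixed: hotspot means dose > 110% of prescription
localization_tol_mm: 1          # BB/user-origin vs localization point agreement
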