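# Example nonzero tolerance overrides for TPS-vs-OIS plan comparison.
# Keys are field-path globs matched against discrepancy field paths;
# values are tolerances in the field's native units. The shipped default
# profile is all-zero: any numeric difference is flagged. Nonzero entries
# exist only to absorb known import/export rounding between systems.
default: 0
overrides:
  "beams[*].mu": 0.01                              # MU rounding on export
  "beams[*].isocenter[*]": 0.1                     # mm
  "beams[*].gantry_angle": 0.1                     # degrees
  "beams[*].collimator_angle": 0.1                 # degrees
  "beams[*].couch_angle": 0.1                      # degrees
  "beams[*].jaws.*": 0.1                           # mm
  "beams[*].control_points[*].mlc_bank_A[*]": 0.1  # mm
  "beams[*].control_points[*].mlc_bank_B[*]": 0.1  # mm
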