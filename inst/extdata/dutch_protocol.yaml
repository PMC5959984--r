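# PTV-size-based single-fraction SRS prescription protocol (Dutch consensus).
# Bins are half-open [previous upper, upper); the last bin is closed at its
# upper edge, which doubles as the SRS eligibility limit.
protocol:
  - {max_volume_cm3: 1, dose_gy: 24}
  - {max_volume_cm3: 10, dose_gy: 21}
  - {max_volume_cm3: 20, dose_gy: 18}
  - {max_volume_cm3: 65, dose_gy: 15}
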