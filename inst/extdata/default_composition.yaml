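# Default synthetic corpus composition: 9,237 included vocalizations
# (per-infant per-month counts) plus 1,751 planted-excluded records,
# ground-truth category mixture 39/21/7/3/30 (SA/DA/TA/MA/SEG).
seed: 1
counts:
  inf01: [47, 7, 92, 71, 199, 44, 25, 0, 37, 2, 0, 0]
  inf02: [84, 103, 112, 198, 11, 18, 12, 0, 21, 16, 0, 0]
  inf03: [79, 82, 151, 138, 21, 94, 74, 15, 20, 26, 22, 0]
  inf04: [8, 134, 158, 141, 200, 99, 0, 0, 0, 54, 123, 0]
  inf05: [81, 87, 105, 124, 104, 85, 0, 81, 60, 76, 136, 0]
  inf06: [104, 200, 295, 266, 149, 127, 54, 40, 74, 92, 56, 0]
  inf07: [0, 149, 0, 0, 68, 150, 68, 97, 152, 122, 72, 0]
  inf08: [49, 267, 24, 0, 0, 0, 0, 10, 141, 30, 168, 37]
  inf09: [64, 139, 0, 0, 196, 35, 40, 121, 141, 163, 33, 153]
  inf10: [144, 148, 0, 0, 133, 224, 93, 174, 120, 56, 199, 123]
sex:
  inf01: male
  inf02: female
  inf03: female
  inf04: female
  inf05: female
  inf06: male
  inf07: female
  inf08: male
  inf09: female
  inf10: male
mixture:
  SA: 0.39
  DA: 0.21
  TA: 0.07
  MA: 0.03
  SEG: 0.30
n_excluded: 1751
too_short_frac: 0.5
type_ratio_early:
  C: 1141
  NC: 4667
type_ratio_late:
  BM: 2754
  BC: 675
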