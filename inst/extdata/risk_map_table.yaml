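# Example per-score lookup risk map (table mode). In table mode the map must
# define a probability for every score attainable under the point table in
# use; this example covers the toy table (max attainable 20).
mode: table
table:
  0: 0.0008
  1: 0.0009
  2: 0.0011
  3: 0.0012
  4: 0.0014
  5: 0.0017
  6: 0.0019
  7: 0.0022
  8: 0.0026
  9: 0.0030
  10: 0.0031
  11: 0.0040
  12: 0.0047
  13: 0.0054
  14: 0.0063
  15: 0.0073
  16: 0.0084
  17: 0.0098
  18: 0.0113
  19: 0.0131
  20: 0.0139
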