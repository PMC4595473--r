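variant: M146L
occupancy:
  KC00L: 1.0
  KC20L: 7.061
  KC30L: 1.778
  KC32L: 274900.0
  KC04L: 174600000.0
  KC04I: 43650000.0
  KC24H: 308200000.0
  KC24I: 308230000.0
  KC34L: 103190000.0
  KO14I: 84780000.0
  KO24H: 3992000000.0
  KO24I: 100600000.0
flux:
  j0414: 1017000.0
  j1424: 28400000.0
  j2434: 496100.0
  j0414IL: 950200000.0
  j1424IL: 640000.0
  j2434IL: 2431.0
  j2030: 0.002449
  j0414II: 25870000.0
  j2424II: 30577000.0
  j2424: 330100.0
  j0404: 54590.0
  j2424HH: 175300000.0
  j3132: 0.02891
  j3334: 2120.0
  j0001: 0.01138
  j0304: 47560000000.0
  j2021: 0.0008904
  j2324: 8523000.0
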