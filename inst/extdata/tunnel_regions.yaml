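# Catalytic-tunnel nomenclature for the Smlt1473 pH-series structures.
# Residue ids are one-letter code + author residue number, single chain.
# Note: the interaction tables label R312 as surface F1 while the
# structural description places it in F2; the F2 assignment is kept here
# and can be overridden from a user config.
surfaces:
  R1: [S45, V46, I47, P49, Q217]
  oLW: [Q53, D57, A60, P61]
  F1: [R64, Y65, D68, R71, D74]
  oRW: [L278, P279, L280, Q281, R305, G306, P307, F308, H309]
  R2: [Y39, R218]
  iLW: [Y38, Q52, N55, K56]
  F2: [D63, R312]
  iRW: [W171, H221, Y222, Y225]
  exit_ring_i: [Y115, R215, N166]
  exit_ring_ii: [K42, K162, R163, N109, N110, D111]
sites:
  entry: [Q52, K56, D63, R218, H221, R312]
  tunnel: [Y38, Y39, N55, W119, W171, Y222, Y225]
  exit: [K42, N110, Q112, Y115, K162, R163, N166, N167, H168, E212, R215]
  catalytic: [Q112, N167, H168, Y222]
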