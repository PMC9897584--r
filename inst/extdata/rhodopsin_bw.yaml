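# Ballesteros-Weinstein numbering configuration for the rod opsin reference.
# anchors: 1-based position of each helix's most conserved (x.50) residue in
# the reference sequence (N55, D83, R135, W161, P215, P267, P303).
# helix_bounds: approximate transmembrane helix spans in reference numbering,
# from the rhodopsin crystal structure. Editable: both blocks are inputs,
# not constants of the method.
reference_id: OPSD_HUMAN
anchors:
  "1": 55
  "2": 83
  "3": 135
  "4": 161
  "5": 215
  "6": 267
  "7": 303
helix_bounds:
  "1": [34, 64]
  "2": [71, 100]
  "3": [106, 140]
  "4": [150, 173]
  "5": [200, 230]
  "6": [246, 277]
  "7": [285, 309]
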