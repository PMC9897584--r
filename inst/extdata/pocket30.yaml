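# Default 30-position cavity-facing pocket used for GPCR profile comparison,
# in Ballesteros-Weinstein labels. Curated from the standard chemogenomic
# TM-cavity position set; includes the retinal-relevant positions 3.28
# (rhodopsin E113) and 7.43 (rhodopsin K296). Editable configuration: swap
# in any position list of interest.
source: curated TM-cavity set (30 positions)
labels:
  - "1.39"
  - "2.53"
  - "2.56"
  - "2.57"
  - "2.60"
  - "2.61"
  - "2.64"
  - "3.28"
  - "3.29"
  - "3.32"
  - "3.33"
  - "3.36"
  - "3.37"
  - "3.40"
  - "4.56"
  - "4.60"
  - "5.38"
  - "5.39"
  - "5.42"
  - "5.43"
  - "5.46"
  - "5.47"
  - "6.44"
  - "6.48"
  - "6.51"
  - "6.52"
  - "6.55"
  - "6.58"
  - "7.39"
  - "7.43"
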