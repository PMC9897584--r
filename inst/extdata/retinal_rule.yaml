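# Retinal-binding rule for visual opsin candidates.
# schiff_position: BW label of the Schiff-base lysine (rhodopsin K296).
# counterion_position: BW label of the counter-ion (rhodopsin E113).
# minimal_pocket: 4 BW labels for the minimal functional pocket check;
# deliberately left empty here - the check runs only when the user supplies
# the four positions of interest.
schiff_position: "7.43"
counterion_position: "3.28"
minimal_pocket: []
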