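# Species distribution of non-redundant top translated-search hits reported
# for the soybean aphid gut and whole-aphid transcriptomes. The published
# per-species gut column sums to 10,652 while the published gut total (and
# the denominator of the published percentages) is 10,640.
species	gut_hits	wa_hits
Acyrthosiphon pisum	8730	11141
Other aphid species	104	110
Tribolium castaneum	120	223
Mosquitos	131	233
Drosophila spp.	151	262
Pediculus humanus	95	163
Harpegnathos saltator	56	85
Camponotus floridanus	49	84
Nasonia vitripennis	64	84
Solenopsis invicta	41	67
Acromyrmex echinatior	31	50
Apis mellifera	43	64
Bombus impatiens	30	49
Bombus terrestris	35	36
Danaus plexippus	34	65
Buchnera aphidicola	20	602
Wolbachia	0	3
Others	918	1530
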