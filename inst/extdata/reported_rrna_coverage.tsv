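# Assembled coverage of Wolbachia wRi rRNA molecules reported for the
# whole-aphid transcriptome: union of contig-aligned reference nucleotides.
# (The published 23S percentage, 76%, is inconsistent with its own printed
# inputs, which give about 61%.)
molecule	covered_nt	ref_len
16S	1070	1505
23S	1686	2746
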