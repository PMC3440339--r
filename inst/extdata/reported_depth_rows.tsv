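# qRT-PCR comparison rows reported for the soybean aphid gut transcriptome:
# reads assembled per contig, contig length, and the published per-nt depth
# (number of reads x 75 nt / contig length). The FT1 row is internally
# inconsistent with the formula on its own printed inputs.
transcript	qpcr_relative_abundance	reads_assembled	contig_len	reported_depth
FT1	1.00	2775	934	222.80
FT2	8.04	1725	520	248.79
APN3	25.46	31032	2725	854.09
APN4	24.84	29218	1471	1489.70
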