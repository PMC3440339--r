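# Pea aphid gene sets and the numbers of putative soybean aphid homologs
# reported per set (gut, whole aphid, and either).
gene_group	n_pea_aphid_genes	gut_recovered	wa_recovered	total_recovered
Amino acid biosynthesis	82	69	70	71
Amino acid degradation	119	99	99	101
Amino acid transporters	47	35	44	45
Cathepsins	74	35	39	39
Chitinase-like proteins	9	7	8	8
Chromatin remodeling proteins	145	71	94	94
Clock genes	14	11	11	12
Developmental	315	187	268	270
Homeobox	55	15	43	44
Immune and stress	98	54	68	68
Ion channels	85	30	66	66
Meiosis and cell cycle	80	43	64	65
Nuclear receptors	14	8	11	11
Purine metabolism and urea cycle	52	34	44	44
Sugar transporters	75	51	69	71
Transcytosis	146	94	115	117
Wing development	20	6	19	19
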