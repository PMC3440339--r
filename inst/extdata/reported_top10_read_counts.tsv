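# Ten most abundant transcripts reported for the soybean aphid gut and
# whole-aphid (WA) transcriptomes: reads assembled per contig.
sample	rank	putative_gene	reads_assembled
gut	1	membrane alanyl aminopeptidase N	65316
gut	2	sugar transporter 1	42057
gut	3	membrane alanyl aminopeptidase N	31032
gut	4	membrane alanyl aminopeptidase N	29218
gut	5	putative cathepsin B-S	22217
gut	6	putative ADP/ATP translocase	21521
gut	7	glutamine synthetase 2	20208
gut	8	alkaline phosphatase homologues	19840
gut	9	Ac1147-like protein	16889
gut	10	cathepsin B-16A	14523
wa	1	similar to cytochrome P450	6741
wa	2	similar to AGAP010734-PA, partial	6057
wa	3	similar to Collagen	5934
wa	4	DnaJ-like protein	5554
wa	5	similar to cement precursor protein 3B	5029
wa	6	ATP synthase-beta	5028
wa	7	similar to paramyosin, long form	5023
wa	8	similar to Mitochondrial phosphate carrier protein	5009
wa	9	similar to tyrosine hydroxylase	4616
wa	10	similar to proteophosphoglycan ppg1	4316
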