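# Overlap of the non-redundant translated-search hit sets reported for the
# gut and whole-aphid (WA) transcriptomes.
category	count
shared	9244
gut_only	1396
wa_only	5617
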