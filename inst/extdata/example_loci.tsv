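locus_id	reference	spacer	spacer_strand	spacer_start	pam	desired_edits
demoA	TGCTTGACCTGTAGGTCATTGCGACTGAACGACAAACATACAATGCTGCTTGGGTCCTAGGTTACGGATCTTGAGCTTACGTC	GACAAACATACAATGCTGCT	sense	30	TGG	5:A>G
demoB	GGATCCTTAGCAGTCGGTTCAGGCTTCAAGCTAGACAATGCAGTACCATGAGGTCGATTCAGGCATGCAAGGTTCCAGTTCGA	CTAGACAATGCAGTACCATG	sense	30	AGG	7:A>G
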