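##gff-version 3
##sequence-region chromosome 1 4641652
# SYNTHETIC fixture: a hand-written mirror of the E. coli K-12 MG1655
# envC-sddA (yibP-yibQ) locus, NOT extracted from a real annotation file.
# It encodes the published operon arrangement -- both genes co-oriented,
# with the envC stop codon and the sddA start codon separated by 3 bp --
# with realistic gene lengths at an approximate chromosomal position, so
# the gap definition can be exercised on a realistic record. Do not use as
# a source of real K-12 coordinates.
chromosome	septolink_synth	gene	3785000	3786259	.	+	.	ID=envC;genome_id=ECOLI_K12_SYNTH;kegg=K22719
chromosome	septolink_synth	gene	3786263	3787222	.	+	.	ID=sddA;genome_id=ECOLI_K12_SYNTH;pfam=PF04748;kegg=K09798
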