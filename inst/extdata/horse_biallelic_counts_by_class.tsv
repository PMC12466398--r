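class	snps	indels	total
intergenic_variant	13745973	1243963	14989936
intron_variant	3359772	351967	3711739
upstream_gene_variant	557181	60416	617597
downstream_gene_variant	229356	24047	253403
5_prime_UTR_variant	132691	14854	147545
3_prime_UTR_variant	71784	8073	79857
missense_variant	62111	0	62111
synonymous_variant	42319	0	42319
non_coding_transcript_exon_variant	23580	1289	24869
splice_region_variant	13331	2009	15340
frameshift_variant	0	4444	4444
splice_donor_variant	2610	323	2933
stop_gained	2336	64	2400
start_lost	988	49	1037
splice_acceptor_variant	669	156	825
inframe_deletion	0	801	801
stop_lost	509	12	521
inframe_insertion	0	403	403
stop_retained_variant	126	7	133
protein_altering_variant	0	22	22
coding_sequence_variant	2	5	7
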