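chrom	pos	ref	alt	a1	a2	variant_type	gene	phenotype	omia_id
3	36979560	C	T	T	C	missense	MC1R	coat color, chestnut	OMIA:001199-9796
3	79538738	C	T	T	C	missense	KIT	white spotting	OMIA:000209-9796
3	79548220	T	C	T	C	missense	KIT	coat color, dominant white	OMIA:000209-9796
3	79566881	T	C	C	T	missense	KIT	increased white spotting	OMIA:000209-9796
16	21555811	C	AAAT	A	C	deletion	MITF	splashed white	OMIA:000214-9796
16	21608936	C	T	C	A	regulatory	MITF	white splashing	OMIA:000214-9796
23	22391254	C	A	A	C	stop-gain	DMRT3	gaitedness	OMIA:001715-9796
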