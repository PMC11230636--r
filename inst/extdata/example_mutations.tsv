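Tumor_Sample_Barcode	Hugo_Symbol	Protein_position	Reference_AA	Alternate_AA	Variant_Classification
S001	TP53	175	R	H	Missense_Mutation
S001	CTNNB1	45	S	F	Missense_Mutation
S002	TP53	273	R	C	Missense_Mutation
S002	AXIN1	500	Q	*	Nonsense_Mutation
S003	TP53	213	R	X	Frame_Shift_Del
S003	CTNNB1	41	T	T	Silent
S004	ARID1A	2285	P	L	Missense_Mutation
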