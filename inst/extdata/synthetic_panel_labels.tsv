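id	label
REF_I-N_1	I-N
REF_I-N_2	I-N
REF_I-N_3	I-N
REF_I-C_1	I-C
REF_I-C_2	I-C
REF_I-C_3	I-C
REF_IIa_1	IIa
REF_IIa_2	IIa
REF_IIa_3	IIa
REF_IIb_1	IIb
REF_IIb_2	IIb
REF_IIb_3	IIb
REF_IIc_1	IIc
REF_IIc_2	IIc
REF_IIc_3	IIc
REF_IId_1	IId
REF_IId_2	IId
REF_IId_3	IId
REF_IIe_1	IIe
REF_IIe_2	IIe
REF_IIe_3	IIe
REF_III_1	III
REF_III_2	III
REF_III_3	III
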