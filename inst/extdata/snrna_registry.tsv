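species	snrna	length_nt	spliceosome
Hsap	U1	164	major
Hsap	U2	187	major
Hsap	U4	145	major
Hsap	U5	116	major
Hsap	U6	107	major
Hsap	U11	135	minor
Hsap	U12	150	minor
Hsap	U4atac	130	minor
Hsap	U6atac	125	minor
Dmel	U1	164	major
Dmel	U2	192	major
Dmel	U4	144	major
Dmel	U5	116	major
Dmel	U6	107	major
Dmel	U11	275	minor
Dmel	U12	238	minor
Dmel	U4atac	160	minor
Dmel	U6atac	110	minor
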