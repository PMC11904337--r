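EXAMPLE_SET_01	synthetic example gene set	GENE0298	GENE0467	GENE0415	GENE0476	GENE0615	GENE0706	GENE0783	GENE0218	GENE0630	GENE0392	GENE0835	GENE0472	GENE0168	GENE0022	GENE0431	GENE0904	GENE0571	GENE0090	GENE0268	GENE0947
EXAMPLE_SET_02	synthetic example gene set	GENE0916	GENE0808	GENE0287	GENE0207	GENE0134	GENE0400	GENE0150	GENE0187	GENE0533	GENE0900	GENE0907	GENE0870	GENE0282	GENE0215	GENE0898	GENE0612	GENE0678	GENE0248	GENE0171	GENE0456
EXAMPLE_SET_03	synthetic example gene set	GENE0636	GENE0977	GENE0891	GENE0462	GENE0292	GENE0249	GENE0515	GENE0877	GENE0693	GENE0088	GENE0553	GENE0181	GENE0278	GENE0776	GENE0429	GENE0041	GENE0543	GENE0290	GENE0288	GENE0908
EXAMPLE_SET_04	synthetic example gene set	GENE0405	GENE0840	GENE0186	GENE0856	GENE0586	GENE0174	GENE0378	GENE0488	GENE0827	GENE0752	GENE0626	GENE0343	GENE0389	GENE0032	GENE0934	GENE0707	GENE0885	GENE0233	GENE0512	GENE0464
EXAMPLE_SET_05	synthetic example gene set	GENE0830	GENE0055	GENE0072	GENE0796	GENE0272	GENE0690	GENE0018	GENE0552	GENE0349	GENE0678	GENE0266	GENE0621	GENE0576	GENE0734	GENE0760	GENE0935	GENE0377	GENE0121	GENE0824	GENE0790
EXAMPLE_SET_06	synthetic example gene set	GENE0172	GENE0006	GENE0196	GENE0752	GENE0043	GENE0845	GENE0364	GENE0759	GENE0124	GENE0274	GENE0225	GENE0529	GENE0801	GENE0300	GENE0971	GENE0288	GENE0048	GENE0162	GENE0233	GENE0570
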