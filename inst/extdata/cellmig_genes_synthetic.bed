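chr2	55199999	55300000	RTN4
chr3	188889999	188895000	SST
chr4	55607651	55616597	KDR
chr6	128485527	128871092	PTPRK
chr11	1094625	1110000	MUC2
chr11	1129999	1140711	MUC5AC
chr12	50532204	50579767	ACVRL1
chr15	50829999	50840000	ONECUT1
chr15	97499999	97600000	IGF1R
chr16	29499999	29600000	CORO1A
chr16	82119366	82502970	CDH13
chr18	52899999	52930000	ONECUT2
chr18	59018002	59031365	BCL2
chr19	50099999	50105000	APOE
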