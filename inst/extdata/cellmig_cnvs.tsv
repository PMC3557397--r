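sample_id	chrom	start	end	copy_number	n_markers	confidence	caller
165855	chr4	55607652	55616597	1	12	10	primary_caller
232996	chr6	128485528	128525520	1	40	10	primary_caller
190037	chr6	128864684	128871092	1	8	10	primary_caller
210711	chr11	1094626	1140711	3	46	10	primary_caller
124873	chr16	29474810	30099408	1	400	10	primary_caller
233682	chr16	29488112	30085920	1	380	10	primary_caller
224567	chr16	82119367	82175095	1	56	10	primary_caller
232030	chr16	82408574	82502970	1	94	10	primary_caller
203688	chr18	52763504	53341297	3	300	10	primary_caller
231734	chr18	59018003	59031365	1	13	10	primary_caller
M3088A	chr2	55119289	56699138	3	800	10	primary_caller
M1270A	chr3	188880305	188936673	3	56	10	primary_caller
M3576A	chr12	50532205	50579767	3	48	10	primary_caller
M3047A	chr15	50811752	50882082	3	70	10	primary_caller
M053A	chr15	97371582	97730964	3	359	10	primary_caller
M3381A	chr19	49893892	50298979	3	405	10	primary_caller
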