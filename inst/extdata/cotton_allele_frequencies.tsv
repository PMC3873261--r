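trait	marker_id	allele	CK	I	II	III	IV	V	VI	Total
BN	NAU6584	2	0.3333	0.5000	0.6923	0.7692	0.6747	0.4720	0.7755	0.6096
LY	NAU3269	2	0.6667	0.5769	0.5385	0.6154	0.3976	0.3040	0.1020	0.3736
BW	BNL1414	2	0.5000	0.3077	0.1923	0.4872	0.2410	0.2320	0.1633	0.2612
LP	NAU5166	2	0.0000	0.0000	0.0000	0.0500	0.0000	0.0320	0.0417	0.0225
LP	NAU2508	2	0.4000	0.1200	0.2400	0.2250	0.3012	0.3952	0.4694	0.3333
LP	NAU980	3	0.0000	0.0200	0.0000	0.0256	0.0244	0.0369	0.0000	0.0233
LP	JESPR135	1	1.0000	0.8462	1.0000	1.0000	0.9759	0.9840	1.0000	0.9775
LI	Gh369	3	0.0000	0.0000	0.0000	0.0000	0.0241	0.0480	0.0000	0.0225
BW	NAU4047	2	0.6667	0.5000	0.5769	0.6154	0.5663	0.6400	0.7551	0.6208
BW	NAU3398	2	0.0000	0.0385	0.0000	0.1026	0.0843	0.0720	0.0204	0.0618
LY	JESPR204	1	1.0000	0.8462	0.8077	0.7692	0.8675	0.9200	0.9388	0.8820
LI	CIR246	3	0.0000	0.0000	0.0000	0.0256	0.0241	0.0800	0.0612	0.0449
LP	BNL3590	1	0.5000	0.8077	0.8462	0.8462	0.9036	0.9440	0.8776	0.8904
LI	NAU2233	1	0.6667	0.4231	0.5000	0.3590	0.5542	0.6560	0.8163	0.5955
LY	TMK19	2	0.6667	0.5000	0.5769	0.6667	0.6024	0.7280	0.8163	0.6742
SI	NAU493	1	0.6667	0.5000	0.7308	0.6923	0.6265	0.6800	0.5714	0.6461
LY	NAU3100	2	0.3333	0.2308	0.0769	0.2308	0.2289	0.2400	0.3673	0.2444
BW	JESPR208	2	0.5000	0.3077	0.1154	0.4359	0.2289	0.2240	0.1633	0.2444
LY	NAU2776	1	0.1667	0.4231	0.3462	0.5385	0.4458	0.4480	0.3061	0.4242
LI	NAU3917	2	0.0000	0.0000	0.0000	0.0513	0.0000	0.0240	0.0204	0.0169
LP	BNL1404	1	1.0000	0.8462	1.0000	1.0000	0.9759	0.9840	1.0000	0.9775
LP	Gh508	1	1.0000	0.9231	1.0000	0.9750	1.0000	0.9920	1.0000	0.9888
LP	NAU2361	3	0.2143	0.0769	0.0417	0.1538	0.1125	0.2810	0.3673	0.2066
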