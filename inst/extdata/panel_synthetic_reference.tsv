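# umprofiler panel definition -- SYNTHETIC RECONSTRUCTION
# coordinates are approximate hg19 intervals / invented SNP loci; structure matches the reference panel
# amplicon_count=418
[regions]
chrom	start	end	gene	pool	mode
9	80409373	80412505	GNAQ	1	HOTSPOT
19	3118922	3119210	GNA11	2	HOTSPOT
13	49281214	49283572	CYSLTR2	1	HOTSPOT
20	9389321	9392076	PLCB4	2	HOTSPOT
3	52435020	52444366	BAP1	1	FULL_CDS
X	20142636	20156000	EIF1AX	2	HOTSPOT
2	198266124	198274737	SF3B1	1	HOTSPOT
17	74730197	74733493	SRSF2	2	FULL_CDS
9	21967751	21995300	CDKN2A	1	FULL_CDS
4	104030000	104105000	CENPE	2	FULL_CDS
13	41129800	41240734	FOXO1	1	FULL_CDS
14	62162119	62214977	HIF1A	2	FULL_CDS
1	93297600	93307500	RPL5	1	FULL_CDS
17	7571720	7590868	TP53	2	FULL_CDS
7	140453075	140453193	BRAF	1	HOTSPOT
[snps]
rsid	chrom	arm	pos
rs90000001	1	p	2300000
rs90000002	1	p	17137500
rs90000003	1	p	31975000
rs90000004	1	p	46812500
rs90000005	1	p	61650000
rs90000006	1	p	76487500
rs90000007	1	p	91325000
rs90000008	1	p	106162500
rs90000009	1	p	1.21e+08
rs90000010	1	q	125100000
rs90000011	1	q	140587500
rs90000012	1	q	156075000
rs90000013	1	q	171562500
rs90000014	1	q	187050000
rs90000015	1	q	202537500
rs90000016	1	q	218025000
rs90000017	1	q	233512500
rs90000018	1	q	2.49e+08
rs90000019	3	p	2e+06
rs90000020	3	p	1.3e+07
rs90000021	3	p	2.4e+07
rs90000022	3	p	3.5e+07
rs90000023	3	p	4.6e+07
rs90000024	3	p	5.7e+07
rs90000025	3	p	6.8e+07
rs90000026	3	p	7.9e+07
rs90000027	3	p	9e+07
rs90000028	3	q	93550000
rs90000029	3	q	106593750
rs90000030	3	q	119637500
rs90000031	3	q	132681250
rs90000032	3	q	145725000
rs90000033	3	q	158768750
rs90000034	3	q	171812500
rs90000035	3	q	184856250
rs90000036	3	q	197900000
rs90000037	8	p	1500000
rs90000038	8	p	6787500
rs90000039	8	p	12075000
rs90000040	8	p	17362500
rs90000041	8	p	22650000
rs90000042	8	p	27937500
rs90000043	8	p	33225000
rs90000044	8	p	38512500
rs90000045	8	p	43800000
rs90000046	8	q	46900000
rs90000047	8	q	57944444
rs90000048	8	q	68988889
rs90000049	8	q	80033333
rs90000050	8	q	91077778
rs90000051	8	q	102122222
rs90000052	8	q	113166667
rs90000053	8	q	124211111
rs90000054	8	q	135255556
rs90000055	8	q	146300000
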