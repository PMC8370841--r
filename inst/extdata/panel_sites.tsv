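gene	rsid	category	ref	alt	star	default_af
CYP2C19	rs12248560	pk_enzyme	C	T	*17	0.21
CYP2C19	rs28399504	pk_enzyme	A	G	*4	0.002
CYP2C19	rs41291556	pk_enzyme	T	C	*8	0.003
CYP2C19	rs4244285	pk_enzyme	G	A	*2	0.15
CYP2C19	rs4986893	pk_enzyme	G	A	*3	0.02
CYP2C19	rs56337013	pk_enzyme	C	T	*5	0.001
CYP2C19	rs72552267	pk_enzyme	G	A	*6	0.001
CYP2C19	rs72558186	pk_enzyme	T	A	*7	0.001
CYP2C9	rs9332239	pk_enzyme	C	T	*12	0.002
CYP2C9	rs9332131	pk_enzyme	A	D	*6	0.002
CYP2C9	rs7900194	pk_enzyme	G	A	*8	0.02
CYP2C9	rs72558190	pk_enzyme	C	T	*13	0.002
CYP2C9	rs72558189	pk_enzyme	A	T	*14	0.002
CYP2C9	rs28371686	pk_enzyme	C	G	*5	0.005
CYP2C9	rs1799853	pk_enzyme	C	T	*2	0.12
CYP2C9	rs1057910	pk_enzyme	A	C	*3	0.07
CYP2C9	rs28371685	pk_enzyme	C	T	*11	0.005
CYP2C9	rs56165452	pk_enzyme	T	C	*4	0.002
CYP2D6	rs59421388	pk_enzyme	G	A	*29	0.02
CYP2D6	rs5030867	pk_enzyme	A	C	*7	0.001
CYP2D6	rs5030865	pk_enzyme	G	T	*8	0.001
CYP2D6	rs5030656	pk_enzyme	A	D	*9	0.02
CYP2D6	rs5030655	pk_enzyme	T	D	*6	0.01
CYP2D6	rs3892097	pk_enzyme	G	A	*4	0.18
CYP2D6	rs35742686	pk_enzyme	A	D	*3	0.01
CYP2D6	rs28371725	pk_enzyme	G	A	*41	0.09
CYP2D6	rs5030862	pk_enzyme	G	A	*12	0.001
CYP2D6	rs16947	pk_enzyme	C	T	*2	0.34
CYP2D6	rs28371735	pk_enzyme	C	T	*59	0.005
CYP2D6	rs1065852	pk_enzyme	C	T	*10	0.22
CYP2D6	rs5030863	pk_enzyme	C	G	*11	0.001
CYP2D6	rs28371706	pk_enzyme	C	T	*17	0.06
CYP2D6	rs72549357	pk_enzyme	T	I	*15	0.001
CYP2B6	rs2279343	pk_enzyme	A	G	*4	0.25
CYP2B6	rs3211371	pk_enzyme	C	T	*5	0.10
CYP2B6	rs3745274	pk_enzyme	G	T	*9	0.28
CYP2B6	rs8192709	pk_enzyme	C	T	*2	0.05
CYP2B6	rs28399499	pk_enzyme	T	C	*18	0.02
F5	rs6025	non_scored	C	T	NA	0.02
SLCO1B1	rs4149056	transporter	T	C	*5	0.15
VKORC1	rs9923231	non_scored	C	T	NA	0.38
VKORC1	rs9934438	non_scored	G	A	NA	0.38
UNASSIGNED_ROW8	rs2952768	other_pd	C	T	NA	0.35
CYP1A2	rs2069514	pk_enzyme	G	A	*1C	0.08
CYP1A2	rs762551	pk_enzyme	A	C	*1F	0.31
CYP3A4	rs35599367	pk_enzyme	C	T	*22	0.05
CYP3A5	rs776746	pk_enzyme	C	T	*3	0.72
APOE	rs7412	non_scored	C	T	NA	0.08
ABCB1	rs1045642	transporter	C	T	NA	0.48
ABCB1	rs2032583	transporter	T	C	NA	0.12
ADRA2A	rs1800544	receptor	C	G	NA	0.30
ADRB1	rs1801253	receptor	C	G	NA	0.27
ADRB1	rs1801252	receptor	A	G	NA	0.14
ADRB2	rs1042713	receptor	G	A	NA	0.38
BDNF	rs6265	other_pd	G	A	NA	0.20
CACNA1C	rs1006737	other_pd	G	A	NA	0.33
CNR1	rs806368	receptor	T	C	NA	0.23
CNR1	rs1049353	receptor	G	A	NA	0.24
CHRNB2	rs2072661	receptor	A	G	NA	0.23
COMT	rs13306278	other_pd	C	T	NA	0.10
COMT	rs165599	other_pd	A	G	NA	0.31
COMT	rs6269	other_pd	A	G	NA	0.42
COMT	rs4680	other_pd	G	A	NA	0.48
COQ2	rs4693075	other_pd	C	G	NA	0.42
DRD1	rs4532	receptor	A	G	NA	0.36
DRD2	rs1799732	receptor	C	D	NA	0.11
DRD2	rs1799978	receptor	T	C	NA	0.05
DRD2	rs1800497	receptor	G	A	NA	0.32
DRD3	rs6280	receptor	T	C	NA	0.33
FAAH	rs324420	other_pd	C	A	NA	0.21
FKBP5	rs4713916	other_pd	G	A	NA	0.30
GNB3	rs5443	other_pd	C	T	NA	0.31
GRIA1	rs1994862	receptor	A	G	NA	0.40
GRIK4	rs1954787	receptor	T	C	NA	0.42
HLA-B	rs2395029	non_scored	T	G	NA	0.03
HLA-B	rs2844682	non_scored	C	T	NA	0.25
HSPG2	rs2445142	other_pd	G	C	NA	0.40
HTR1A	rs6295	receptor	C	G	NA	0.48
HTR1A	rs10042486	receptor	C	T	NA	0.35
HTR1A	rs1364043	receptor	T	G	NA	0.28
HTR2A	rs6313	receptor	C	T	NA	0.43
HTR2A	rs7997012	receptor	G	A	NA	0.41
HTR2C	rs3813929	receptor	C	T	NA	0.15
HTR2C	rs1414334	receptor	C	G	NA	0.17
MC4R	rs17782313	receptor	T	C	NA	0.24
MTHFR	rs1801133	non_scored	C	T	NA	0.33
MTHFR	rs1801131	non_scored	A	C	NA	0.31
NEDD4L	rs4149601	other_pd	G	A	NA	0.35
OPRD1	rs529520	receptor	A	C	NA	0.40
OPRM1	rs2952768	receptor	C	T	NA	0.35
OPRM1	rs1799971	receptor	A	G	NA	0.16
PRKCA	rs16960228	other_pd	G	A	NA	0.13
POLG	rs3087374	other_pd	G	T	NA	0.08
RGS4	rs951439	other_pd	C	T	NA	0.40
SACM1L	rs2742417	other_pd	A	G	NA	0.30
SLC6A4	SLC6A4_5HTTLPR	transporter	L	S	NA	0.42
SLC6A4	rs25531	transporter	A	G	NA	0.09
SLC6A2	rs2242446	transporter	C	T	NA	0.28
SCN1A	rs3812718	other_pd	G	A	NA	0.47
SCN2A	rs17183814	other_pd	G	A	NA	0.07
TPH1	rs1800532	other_pd	G	T	NA	0.39
TPH2	rs1487278	other_pd	T	C	NA	0.30
UGT1A4	rs2011425	pk_enzyme	T	G	*3	0.08
UGT2B15	rs1902023	pk_enzyme	G	T	*2	0.47
UGT2B15	rs2952768	pk_enzyme	C	T	NA	0.35
YEATS4	rs7297610	other_pd	C	T	NA	0.28
ZNF804A	rs1344706	other_pd	A	C	NA	0.41
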