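gene	allele	chrom	pos	ref	alt	rsid	function	activity	freq_AFR	freq_AMR	freq_EAS	freq_EUR	freq_SAS
ABCG2	*1						normal		0.99	0.86	0.71	0.91	0.91
ABCG2	*2	chr4	88131171	G	T	rs2231142	decreased		0.01	0.14	0.29	0.09	0.09
BCHE	*1						normal		0.985	0.975	0.995	0.96	0.97
BCHE	*A	chr3	165830741	T	G	rs1799807	decreased		0.005	0.01	0	0.015	0.01
BCHE	*K	chr3	165773492	C	T	rs1803274	decreased		0.01	0.015	0.005	0.025	0.02
CACNA1S	*1						normal		0.999	0.999	0.999	0.999	0.999
CACNA1S	*MH1	chr1	201091993	C	T	rs772226819	increased		0.001	0.001	0.001	0.001	0.001
CFTR	*1						normal		0.999	0.998	0.999	0.995	0.999
CFTR	*G551D	chr7	117587806	G	A	rs75527207	increased		0.001	0.002	0.001	0.005	0.001
CYP2B6	*1						normal		0.55	0.7	0.75	0.68	0.55
CYP2B6	*4	chr19	41512841	A	G	rs2279343	increased		0.02	0.03	0.02	0.04	0.02
CYP2B6	*6	chr19	41512541	G	T	rs3745274	decreased		0.38	0.22	0.18	0.22	0.38
CYP2B6	*6	chr19	41512841	A	G	rs2279343	decreased		0.38	0.22	0.18	0.22	0.38
CYP2B6	*9	chr19	41512541	G	T	rs3745274	decreased		0.05	0.05	0.05	0.06	0.05
CYP2C19	*1						normal		0.6	0.75	0.64	0.7	0.55
CYP2C19	*17	chr10	94761900	C	T	rs12248560	increased		0.22	0.12	0.02	0.15	0.14
CYP2C19	*2	chr10	94781859	G	A	rs4244285	no_function		0.17	0.12	0.3	0.15	0.3
CYP2C9	*1						normal		0.97	0.86	0.963	0.805	0.85
CYP2C9	*2	chr10	94942290	C	T	rs1799853	decreased		0.02	0.1	0.001	0.125	0.05
CYP2C9	*3	chr10	94981296	A	C	rs1057910	no_function		0.01	0.04	0.035	0.07	0.1
CYP2D6	*1						normal	1	0.4	0.55	0.35	0.5	0.45
CYP2D6	*10	chr22	42130692	G	A	rs1065852	decreased	0.25	0.08	0.05	0.4	0.02	0.08
CYP2D6	*2	chr22	42127941	C	T	rs16947	normal	1	0.25	0.25	0.12	0.27	0.3
CYP2D6	*4	chr22	42128945	C	T	rs3892097	no_function	0	0.08	0.1	0.005	0.17	0.1
CYP2D6	*5						no_function	0	0.03	0.02	0.05	0.03	0.02
CYP3A5	*1						normal		0.7	0.25	0.29	0.06	0.33
CYP3A5	*3	chr7	99672916	T	C	rs776746	no_function		0.3	0.75	0.71	0.94	0.67
CYP4F2	*1						normal		0.91	0.75	0.78	0.7	0.58
CYP4F2	*3	chr19	15879621	C	T	rs2108622	decreased		0.09	0.25	0.22	0.3	0.42
DPYD	*1						normal		0.95	0.97	0.985	0.96	0.97
DPYD	*2A	chr1	97450058	C	T	rs3918290	no_function		0.001	0.005	0	0.01	0.005
DPYD	*9	chr1	97883329	A	G	rs1801265	normal		0.049	0.025	0.015	0.03	0.025
G6PD	*1						normal		0.87	0.985	0.995	0.988	0.975
G6PD	*A-	chrX	154536002	C	T	rs1050829	decreased		0.12	0.005	0	0.002	0.005
G6PD	*Med	chrX	154532439	C	T	rs5030868	no_function		0.01	0.01	0.005	0.01	0.02
IFNL3	*1						normal		0.4	0.55	0.88	0.65	0.7
IFNL3	*2	chr19	39248147	C	T	rs12979860	uncertain		0.35	0.25	0.06	0.2	0.15
IFNL3	*3	chr19	39252525	T	G	rs8099917	uncertain		0.15	0.12	0.03	0.1	0.1
IFNL3	*4	chr19	39239220	A	G	rs12980275	uncertain		0.1	0.08	0.03	0.05	0.05
MT-RNR1	*1						normal		0.997	0.997	0.995	0.998	0.996
MT-RNR1	*1555G	chrM	1555	A	G	rs267606617	increased		0.003	0.003	0.005	0.002	0.004
NAT2	*1						normal		0.45	0.45	0.6	0.3	0.35
NAT2	*5	chr8	18400344	T	C	rs1801280	decreased		0.3	0.35	0.05	0.45	0.35
NAT2	*6	chr8	18400806	G	A	rs1799930	decreased		0.25	0.2	0.35	0.25	0.3
NUDT15	*1						normal		1	0.95	0.9	0.998	0.93
NUDT15	*3	chr13	48037782	C	T	rs116855232	no_function		0	0.05	0.1	0.002	0.07
RYR1	*1						normal		0.998	0.998	0.998	0.997	0.998
RYR1	*MH1	chr19	38455420	C	T	rs118192172	increased		0.002	0.002	0.002	0.003	0.002
SLCO1B1	*1						normal		0.98	0.87	0.88	0.84	0.91
SLCO1B1	*5	chr12	21178615	T	C	rs4149056	decreased		0.02	0.13	0.12	0.16	0.09
TPMT	*1						normal		0.965	0.949	0.96	0.9595	0.97
TPMT	*3A	chr6	18130918	T	C	rs1142345	no_function		0.01	0.03	0	0.03	0.01
TPMT	*3A	chr6	18139228	C	T	rs1800460	no_function		0.01	0.03	0	0.03	0.01
TPMT	*3B	chr6	18139228	C	T	rs1800460	no_function		0.005	0.001	0	5e-4	0
TPMT	*3C	chr6	18130918	T	C	rs1142345	no_function		0.02	0.02	0.02	0.01	0.02
UGT1A1	*1						normal		0.56	0.62	0.84	0.68	0.6
UGT1A1	*80	chr2	233759924	C	T	rs887829	decreased		0.44	0.38	0.16	0.32	0.4
VKORC1	*1						normal		0.9	0.55	0.12	0.61	0.85
VKORC1	*2	chr16	31096368	G	A	rs9923231	decreased		0.1	0.45	0.88	0.39	0.15
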