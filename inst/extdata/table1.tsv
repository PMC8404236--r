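variant_id	gene	phenotype	syrian_full	syrian_full_pct	ashkenazi	ashkenazi_pct	followed_up
ABCC8:c.3989-9G>A	ABCC8	HYPERINSULINEMIC HYPOGLYCEMIA, FAMILIAL, 1	1/339	0.29	3969/235602	1.68	NO
AGXT:c.731T>C	AGXT	PRIMARY HYPEROXALURIA TYPE 1	4/369	1.08	0/21050	0.00	YES
ARSA:c.449C>T	ARSA	METACHROMATIC LEUKODYSTROPHY	5/376	1.33	1/51587	0.00	YES
ARSA:c.854+3A>G	ARSA	METACHROMATIC LEUKODYSTROPHY	5/376	1.33	0/46388	0.00	YES
BLM:c.2208T>G	BLM	BLOOM SYNDROME	1/404	0.25	3265/335777	0.97	NO
CFTR:c.3846G>A	CFTR	CYSTIC FIBROSIS	3/435	0.69	6721/335635	2.00	NO
CFTR:c.254G>A	CFTR	CYSTIC FIBROSIS	2/381	0.52	0/97562	0.00	YES
CFTR:c.1624G>T	CFTR	CYSTIC FIBROSIS	2/435	0.46	737/335635	0.22	NO
CFTR:c.1521_1523del	CFTR	CYSTIC FIBROSIS	2/438	0.46	3965/335635	1.18	YES
CFTR:c.2989-1G>A	CFTR	CYSTIC FIBROSIS	1/329	0.30	0/223335	0.00	NO
CNGB3:c.467C>T	CNGB3	ACHROMATOPSIA	7/376	1.86	26/44392	0.06	YES
COL6A2:c.1402C>T	COL6A2	ULLRICH CONGENITAL MUSCULAR DYSTROPHY TYPE 1	13/331	3.93	0/5922	0.00	YES
CYP11B1:c.992C>T	CYP11B1	CONGENITAL ADRENAL HYPERPLASIA	10/376	2.66	0/44988	0.00	YES
DHCR7:c.964-1G>C	DHCR7	SMITH-LEMLI-OPITZ SYNDROME	2/227	0.88	2016/88773	2.27	NO
DSE:c.387delC	DSE	EHLERS-DANLOS SYNDROME, MUSCULOCONTRACTURAL TYPE2	1/369	0.27	0/21009	0.00	YES
ESCO2:c.1674-2A>G	ESCO2	ROBERTS SYNDROME	2/376	0.53	0/51519	0.00	YES
FAM161A:c.1567C>T	FAM161A	RETINITIS PIGMENTOSA 28	3/154	1.95	1/49492	0.00	NO
FXN:GAA expansion	FXN	FRIEDREICH ATAXIA	3/331	0.91	14/5109	0.27	YES
G6PC:c.247C>T	G6PC1	GLYCOGEN STORAGE DISEASE TYPE 1A	2/397	0.50	4816/335799	1.43	NO
GBA:c.1448T>C	GBA	GAUCHER DISEASE	1/101	0.99	88/72333	0.12	NO
GJB2:c.167del	GJB2	NONSYNDROMIC DEAFNESS	8/368	2.17	929/32870	2.83	YES
GJB2:c.269T>C	GJB2	NONSYNDROMIC DEAFNESS	1/104	0.96	7/32171	0.02	NO
GNE:c.2228T>C	GNE	INCLUSION BODY MYOPATHY (HIBM)	8/376	2.13	1/51647	0.00	YES
MLC1:c.176G>A	MLC1	MEGALENCEPHALIC LEUKOENCEPHALOPATHY WITH SUBCORTICAL CYSTS 1	1/273	0.37	0/53648	0.00	NO
MMACHC:c.271dup	MMACHC	METHYLMALONIC ACIDURIA AND HOMOCYSTINURIA, cblC TYPE	1/154	0.65	372/49724	0.75	NO
NDUFS4:c.355G>C	NDUFS4	LEIGH SYNDROME TYPE 1	2/376	0.53	0/46275	0.00	YES
OTOF:c.5193-1G>A	OTOF	DEAFNESS, AUTOSOMAL RECESSIVE	4/101	3.96	0/30796	0.00	NO
OTOF:c.4227+1G>T	OTOF	DEAFNESS, AUTOSOMAL RECESSIVE	1/102	0.98	0/30826	0.00	NO
PEX2:c.355C>T	PEX2	PEROXISOME BIOGENESIS DISORDER 5A (ZELLWEGER)	1/154	0.65	379/49883	0.76	NO
SMPD1:c.1829G>A	SMPD1	NIEMANN-PICK DISEASE	1/93	1.08	0/25901	0.00	NO
SMPD1:c.1826_1828GCC	SMPD1	NIEMANN-PICK DISEASE	2/380	0.53	66/304382	0.02	NO
TRPM1:36.8KB DEL	TRPM1	CONGENITAL STATIONARY NIGHT BLINDNESS	2/133	1.50	946/37796	2.50	NO
VAC14:c.2005G>T	VAC14	STRIATONIGRAL DEGENERATION	1/367	0.27	0/30779	0.00	YES
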