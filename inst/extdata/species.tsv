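# Species table: canonical name, diffusion constant D (um^2/s, 0 = anchored),
# and subunit composition as semicolon-separated Moiety:count pairs.
# Compositions drive conserved-moiety accounting (e.g. "Complex" carries two
# CaMKII subunits; the regulatory dimer keeps its four cAMP when the catalytic
# subunit dissociates).  Ade = adenine nucleotide (ATP/cAMP/AMP and bound
# forms); Catot = total calcium (free, external, buffered, pumped, bound).
name	D	composition
Da	150	Da:1
Da_Ext	0	Da:1
R	0	R:1
DaR	0	Da:1;R:1
Gabg	0	Ga:1;Gbg:1
DaRGabg	0	Da:1;R:1;Ga:1;Gbg:1
DaRGbg	0	Da:1;R:1;Gbg:1
GaGTP	0	Ga:1
GaGDP	0	Ga:1
Gbg	0	Gbg:1
GabgR	0	R:1;Ga:1;Gbg:1
AC	0	AC:1
ACGaGTP	0	AC:1;Ga:1
ATP	74.7	Ade:1
ACGaGTP_ATP	0	AC:1;Ga:1;Ade:1
cAMP	86.4	Ade:1
ACCa	0	AC:1;Catot:1
ACGaGTPCa	0	AC:1;Ga:1;Catot:1
ACGaGTPCa_ATP	0	AC:1;Ga:1;Catot:1;Ade:1
PDE1	0	PDE1:1
PDE1CamCa4	0	PDE1:1;Cam:1;Catot:4
PDE1CamCa4cAMP	0	PDE1:1;Cam:1;Catot:4;Ade:1
AMP	85.5	Ade:1
PDE10	0	PDE10:1
PDE10cAMP	0	PDE10:1;Ade:1
pPDE10	0	PDE10:1
pPDE10cAMP	0	PDE10:1;Ade:1
PKAcPDE10	0	PKAc:1;PDE10:1
PKAcPDE10cAMP	0	PKAc:1;PDE10:1;Ade:1
PKAcAMP4PDE10	0	PKAc:2;PKAr:1;Ade:4;PDE10:1
PKAcAMP4PDE10cAMP	0	PKAc:2;PKAr:1;Ade:5;PDE10:1
Ca	174.3	Catot:1
CaOut	0	Catot:1
pmca	0	pmca:1
pmcaCa	0	pmca:1;Catot:1
ncx	0	ncx:1
ncxCa	0	ncx:1;Catot:1
Calbindin	9.3	Calbindin:1
CalbindinCa	9.3	Calbindin:1;Catot:1
Cam	11	Cam:1
CamCa2	11	Cam:1;Catot:2
CamCa4	11	Cam:1;Catot:4
PP2B	0	PP2B:1
PP2BCam	0	PP2B:1;Cam:1
PP2BCamCa2	0	PP2B:1;Cam:1;Catot:2
PP2BCamCa4	0	PP2B:1;Cam:1;Catot:4
CaMKII	3.6	CaMKII:1
CaMKIIp	3.6	CaMKII:1
CaMKIICamCa4	3.6	CaMKII:1;Cam:1;Catot:4
CaMKIIpCamCa4	3.6	CaMKII:1;Cam:1;Catot:4
Complex	0	CaMKII:2;Cam:2;Catot:8
pComplex	0	CaMKII:2;Cam:2;Catot:8
PP1	0	PP1:1
CaMKIIpPP1	0	CaMKII:1;PP1:1
CaMKIIpCamCa4PP1	0	CaMKII:1;Cam:1;Catot:4;PP1:1
PKA	0	PKAc:2;PKAr:1
PKAcAMP2	0	PKAc:2;PKAr:1;Ade:2
PKAcAMP4	0	PKAc:2;PKAr:1;Ade:4
R2CcAMP4	0	PKAc:1;PKAr:1;Ade:4
PKAc	8.1	PKAc:1
PKAr	0	PKAr:1;Ade:4
DARPP32	10.6	DARPP32:1
DARPP32_PKAc	10.6	DARPP32:1;PKAc:1
p34DARPP32	10.6	DARPP32:1
p34DARPP32_PKAcAMP4	0	DARPP32:1;PKAc:2;PKAr:1;Ade:4
p34DARPP32_PP1	0	DARPP32:1;PP1:1
p34DARPP32_PP2BCamCa4	0	DARPP32:1;PP2B:1;Cam:1;Catot:4
p34DARPP32_PP1_PP2BCamCa4	0	DARPP32:1;PP1:1;PP2B:1;Cam:1;Catot:4
PP1_PP2BCamCa4	0	PP1:1;PP2B:1;Cam:1;Catot:4
PP2A_B56d	0	PP2A_B56d:1
PP2A_BPR72	0	PP2A_BPR72:1
p34DARPP32_PP2A_B56d	0	DARPP32:1;PP2A_B56d:1
p34DARPP32_PP2A_BPR72	0	DARPP32:1;PP2A_BPR72:1
p34DARPP32_PP1_PP2A_B56d	0	DARPP32:1;PP1:1;PP2A_B56d:1
p34DARPP32_PP1_PP2A_BPR72	0	DARPP32:1;PP1:1;PP2A_BPR72:1
PP1_PP2A_B56d	0	PP1:1;PP2A_B56d:1
PP1_PP2A_BPR72	0	PP1:1;PP2A_BPR72:1
Cdk5	0	Cdk5:1
Cdk5DARPP32	0	Cdk5:1;DARPP32:1
p75DARPP32	10.6	DARPP32:1
p75DARPP32_PKAc	10.6	DARPP32:1;PKAc:1
PKAcPP2A_B56d	0	PKAc:1;PP2A_B56d:1
pPP2A	0	PP2A_B56d:1
PKAcAMP4PP2A_B56d	0	PKAc:2;PKAr:1;Ade:4;PP2A_B56d:1
CaPP2A	0	PP2A_BPR72:1;Catot:1
p75DARPP32_pPP2A	0	DARPP32:1;PP2A_B56d:1
p75DARPP32_PP2A_B56d	0	DARPP32:1;PP2A_B56d:1
p75DARPP32_PP2A_BPR72	0	DARPP32:1;PP2A_BPR72:1
p75DARPP32_CaPP2A	0	DARPP32:1;PP2A_BPR72:1;Catot:1
GluA1	0	GluA1:1
GluA1_PKAc	0	GluA1:1;PKAc:1
pS845GluA1	0	GluA1:1
GluA1_PKAcAMP4	0	GluA1:1;PKAc:2;PKAr:1;Ade:4
GluA1_CaMKIICamCa4	0	GluA1:1;CaMKII:1;Cam:1;Catot:4
GluA1_CaMKIIpCamCa4	0	GluA1:1;CaMKII:1;Cam:1;Catot:4
GluA1_CaMKIIp	0	GluA1:1;CaMKII:1
pS831GluA1	0	GluA1:1
pS845GluA1_PP1	0	GluA1:1;PP1:1
pS845pS831GluA1	0	GluA1:1
pS845pS831GluA1_PP1	0	GluA1:1;PP1:1
pS845pS831GluA1_PP1_s831	0	GluA1:1;PP1:1
pS831GluA1_PP1	0	GluA1:1;PP1:1
pS845GluA1_PP2B	0	GluA1:1;PP2B:1;Cam:1;Catot:4
pS845pS831GluA1_PP2B	0	GluA1:1;PP2B:1;Cam:1;Catot:4
pS831GluA1_PKAc	0	GluA1:1;PKAc:1
pS831GluA1_PKAcAMP4	0	GluA1:1;PKAc:2;PKAr:1;Ade:4
pS845GluA1_CaMKIICamCa4	0	GluA1:1;CaMKII:1;Cam:1;Catot:4
pS845GluA1_CaMKIIpCamCa4	0	GluA1:1;CaMKII:1;Cam:1;Catot:4
pS845GluA1_CaMKIIp	0	GluA1:1;CaMKII:1
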