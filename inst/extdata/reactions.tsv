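# Reaction table for the striatal dopamine -> cAMP/PKA/DARPP-32 network.
# One row per reaction-table entry, tab separated:
#   equation <TAB> kf <TAB> kb <TAB> kcat <TAB> flag
# Equation dialect:
#   A + B <-> C            reversible (kf forward, kb backward)
#   A -> B                 irreversible (kf only)
#   E + S <-> ES -> E + P  enzyme triple (kf bind, kb unbind, kcat catalyze)
#   2*X                    lumped pair: propensity first order in X, but 2
#                          molecules consumed/released (calmodulin Ca pairs,
#                          cAMP pairs binding the PKA holoenzyme)
#   A + A                  true self pair: propensity kf*[A]^2
# kf is nM^-1 s^-1 for bimolecular steps and s^-1 for unimolecular steps;
# kb and kcat are s^-1 unless the backward step is bimolecular.
# flag: adj (adjusted), pmr (microscopic reversibility), mirror (implied
# phosphosite-independence mirror of a printed row), blank otherwise.
# Dopamine exchange and receptor/G-protein cycle
Da <-> Da_Ext	2	2.00E-05		adj
Da + R <-> DaR	0.00111	10
DaR + Gabg <-> DaRGabg -> DaRGbg + GaGTP	6.00E-04	0.001	20
Gabg + R <-> GabgR	6.00E-05	0.0003
# The catalytic step of the next printed row duplicates the one above, so the
# row enters here as its binding step only (DaRGabg -> DaRGbg + GaGTP at
# 20 s^-1 already exists as an elementary reaction).
GabgR + Da <-> DaRGabg	0.00333	10		pmr
DaRGbg -> DaR + Gbg	80
GaGTP -> GaGDP	10
GaGDP + Gbg -> Gabg	100
# Adenylate cyclase activation and cAMP production
GaGTP + AC <-> ACGaGTP	0.0385	50
ACGaGTP + ATP <-> ACGaGTP_ATP	0.000128	0.2612
ACGaGTP_ATP <-> ACGaGTP + cAMP	28.46	0.000259
AC + Ca <-> ACCa	0.001	0.9
GaGTP + ACCa <-> ACGaGTPCa	0.01923	25
ACGaGTPCa + ATP <-> ACGaGTPCa_ATP	6.38E-05	0.1306
ACGaGTPCa_ATP <-> cAMP + ACGaGTPCa	14.23	0.00013
# Phosphodiesterases
PDE1 + CamCa4 <-> PDE1CamCa4	0.1	1
PDE1CamCa4 + cAMP <-> PDE1CamCa4cAMP -> PDE1CamCa4 + AMP	0.0046	44	11
PKAc + PDE10 <-> PKAcPDE10 -> pPDE10 + PKAc	6.25E-04	0.6022	0.1506	adj
PKAcAMP4 + PDE10 <-> PKAcAMP4PDE10	6.25E-05	0.6022
PKAcAMP4PDE10 <-> PKAcPDE10 + R2CcAMP4	0.38	0.016		pmr
PKAc + PDE10cAMP <-> PKAcPDE10cAMP -> pPDE10cAMP + PKAc	6.25E-04	0.6022	0.1506	adj
PKAcAMP4 + PDE10cAMP <-> PKAcAMP4PDE10cAMP	6.25E-05	0.6022
PKAcAMP4PDE10cAMP <-> PKAcPDE10cAMP + R2CcAMP4	0.38	0.016		pmr
pPDE10 -> PDE10	0.01036			adj
PDE10 + cAMP <-> PDE10cAMP -> PDE10 + AMP	0.084	16.8	4.2
pPDE10 + cAMP <-> pPDE10cAMP -> pPDE10 + AMP	0.1008	16.8	8.4	adj
AMP -> ATP	1			adj
# Calcium handling: pumps, leak, buffers
Ca + pmca <-> pmcaCa -> pmca + CaOut	0.05	7	3.5
Ca + ncx <-> ncxCa -> ncx + CaOut	0.0168	11.2	5.6
CaOut -> Ca	0.0017			adj
Ca + Calbindin <-> CalbindinCa	0.028	19.6
# Calmodulin and its targets
Cam + 2*Ca <-> CamCa2	0.006	9.1
CamCa2 + 2*Ca <-> CamCa4	0.1	1000
Cam + PP2B <-> PP2BCam	0.0046	0.0012		pmr
CamCa2 + PP2B <-> PP2BCamCa2	0.046	0.0012
PP2BCam + 2*Ca <-> PP2BCamCa2	0.006	0.91
CamCa4 + PP2B <-> PP2BCamCa4	0.046	0.0012
PP2BCamCa2 + 2*Ca <-> PP2BCamCa4	0.1	1000		pmr
# CaMKII activation and autophosphorylation
CamCa4 + CaMKII <-> CaMKIICamCa4	0.01	3
CaMKIICamCa4 + CaMKIICamCa4 <-> Complex	0.0001	10
CaMKIIpCamCa4 + CaMKIICamCa4 <-> pComplex	0.0001	10
CaMKIIpCamCa4 + Complex -> CaMKIIpCamCa4 + pComplex	0.0001
CaMKIICamCa4 + Complex -> CaMKIICamCa4 + pComplex	0.0001
Complex + Complex -> Complex + pComplex	0.01
Complex + pComplex -> pComplex + pComplex	0.03
CaMKIIpCamCa4 <-> CamCa4 + CaMKIIp	0.0008	0.01
CaMKIIp + PP1 <-> CaMKIIpPP1 -> PP1 + CaMKII	1.00E-05	0.085	0.025
# PKA holoenzyme activation
PKA + 2*cAMP <-> PKAcAMP2	8.70E-05	0.02
PKAcAMP2 + 2*cAMP <-> PKAcAMP4	1.15E-04	0.2
PKAcAMP4 <-> R2CcAMP4 + PKAc	0.038	0.016
R2CcAMP4 <-> PKAr + PKAc	0.152	0.004		adj
# DARPP-32 phosphorylation and dephosphorylation
DARPP32 + PKAc <-> DARPP32_PKAc -> PKAc + p34DARPP32	0.0027	8	2
p34DARPP32 + PKAcAMP4 <-> p34DARPP32_PKAcAMP4	0.00027	8
p34DARPP32_PKAcAMP4 <-> R2CcAMP4 + DARPP32_PKAc	0.38	0.016		pmr
p34DARPP32 + PP1 <-> p34DARPP32_PP1	0.4	0.58
p34DARPP32 + PP2BCamCa4 <-> p34DARPP32_PP2BCamCa4 -> PP2BCamCa4 + DARPP32	0.000179	2	0.5
p34DARPP32_PP1 + PP2BCamCa4 <-> p34DARPP32_PP1_PP2BCamCa4 -> PP1_PP2BCamCa4 + DARPP32	2.98E-05	0.333	0.0833
PP1_PP2BCamCa4 -> PP2BCamCa4 + PP1	5
p34DARPP32 + PP2A_B56d <-> p34DARPP32_PP2A_B56d -> PP2A_B56d + DARPP32	0.00152	56	14
p34DARPP32 + PP2A_BPR72 <-> p34DARPP32_PP2A_BPR72 -> PP2A_BPR72 + DARPP32	0.00152	56	14
p34DARPP32_PP1 + PP2A_B56d <-> p34DARPP32_PP1_PP2A_B56d -> PP1_PP2A_B56d + DARPP32	0.000253	9.33	2.33
p34DARPP32_PP1 + PP2A_BPR72 <-> p34DARPP32_PP1_PP2A_BPR72 -> PP1_PP2A_BPR72 + DARPP32	0.000253	9.33	2.33
PP1_PP2A_B56d -> PP2A_B56d + PP1	50
PP1_PP2A_BPR72 -> PP2A_BPR72 + PP1	50
Cdk5 + DARPP32 <-> Cdk5DARPP32 -> p75DARPP32 + Cdk5	0.0045	40	10	adj
p75DARPP32 + PKAc <-> p75DARPP32_PKAc	0.00037	1
# PP2A regulation by PKA and calcium
PP2A_B56d + PKAc <-> PKAcPP2A_B56d -> PKAc + pPP2A	0.0025	0.3	0.1
PP2A_B56d + PKAcAMP4 <-> PKAcAMP4PP2A_B56d	0.00025	0.3
PKAcAMP4PP2A_B56d <-> R2CcAMP4 + PKAcPP2A_B56d	0.38	0.016		pmr
pPP2A -> PP2A_B56d	0.004			adj
PP2A_BPR72 + Ca <-> CaPP2A	3.33E-05	0.1
p75DARPP32 + pPP2A <-> p75DARPP32_pPP2A -> DARPP32 + pPP2A	0.03	336	84
p75DARPP32 + PP2A_B56d <-> p75DARPP32_PP2A_B56d -> DARPP32 + PP2A_B56d	0.0046	168	42
p75DARPP32 + PP2A_BPR72 <-> p75DARPP32_PP2A_BPR72 -> DARPP32 + PP2A_BPR72	0.0046	168	42
p75DARPP32 + CaPP2A <-> p75DARPP32_CaPP2A -> CaPP2A + DARPP32	0.03	336	84
# GluA1 phosphorylation (Ser845 by PKA, Ser831 by CaMKII) and dephosphorylation
GluA1 + PKAc <-> GluA1_PKAc -> pS845GluA1 + PKAc	0.00402	24	6
PKAcAMP4 + GluA1 <-> GluA1_PKAcAMP4	0.000402	24
GluA1_PKAcAMP4 <-> R2CcAMP4 + GluA1_PKAc	0.38	0.016		pmr
GluA1 + CaMKIICamCa4 <-> GluA1_CaMKIICamCa4 -> pS831GluA1 + CaMKIICamCa4	2.22E-05	1.6	0.4
GluA1 + CaMKIIpCamCa4 <-> GluA1_CaMKIIpCamCa4 -> pS831GluA1 + CaMKIIpCamCa4	2.78E-05	2	0.5
GluA1 + CaMKIIp <-> GluA1_CaMKIIp -> pS831GluA1 + CaMKIIp	2.22E-05	1.6	0.4
pS845GluA1 + PP1 <-> pS845GluA1_PP1 -> GluA1 + PP1	0.000218	0.17	0.0425
pS845pS831GluA1 + PP1 <-> pS845pS831GluA1_PP1 -> pS831GluA1 + PP1	0.000219	0.35	0.0875
pS831GluA1 + PP1 <-> pS831GluA1_PP1 -> GluA1 + PP1	0.000219	0.35	0.0875
pS845GluA1 + PP2BCamCa4 <-> pS845GluA1_PP2B -> GluA1 + PP2BCamCa4	0.00201	8	2
# Phosphosite-independence mirrors (same rates as the corresponding row above)
pS831GluA1 + PKAc <-> pS831GluA1_PKAc -> pS845pS831GluA1 + PKAc	0.00402	24	6	mirror
PKAcAMP4 + pS831GluA1 <-> pS831GluA1_PKAcAMP4	0.000402	24		mirror
pS831GluA1_PKAcAMP4 <-> R2CcAMP4 + pS831GluA1_PKAc	0.38	0.016		mirror
pS845GluA1 + CaMKIICamCa4 <-> pS845GluA1_CaMKIICamCa4 -> pS845pS831GluA1 + CaMKIICamCa4	2.22E-05	1.6	0.4	mirror
pS845GluA1 + CaMKIIpCamCa4 <-> pS845GluA1_CaMKIIpCamCa4 -> pS845pS831GluA1 + CaMKIIpCamCa4	2.78E-05	2	0.5	mirror
pS845GluA1 + CaMKIIp <-> pS845GluA1_CaMKIIp -> pS845pS831GluA1 + CaMKIIp	2.22E-05	1.6	0.4	mirror
pS845pS831GluA1 + PP1 <-> pS845pS831GluA1_PP1_s831 -> pS845GluA1 + PP1	0.000219	0.35	0.0875	mirror
pS845pS831GluA1 + PP2BCamCa4 <-> pS845pS831GluA1_PP2B -> pS831GluA1 + PP2BCamCa4	0.00201	8	2	mirror
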