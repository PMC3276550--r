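# Basal state of non-anchored pools, as whole-morphology average
# concentrations (nM).  placement:
#   uniform   populate every subvolume in proportion to its volume
#   pde10     populate the configured phosphodiesterase-10 region
#             (dendritic submembrane + spine by default, or uniform)
#   membrane  populate dendritic submembrane + spine subvolumes (pumps);
#             falls back to uniform on meshes without a submembrane region
# The pmca/ncx totals are package calibrations (not printed in the source
# tables): they balance the constitutive calcium leak at the basal calcium
# concentration.  See the methods vignette.
species	conc_nM	placement
Ca	58.7	uniform
CaOut	2005230.1	uniform
Calbindin	145508.3	uniform
CalbindinCa	14329.0	uniform
Da	10.0	uniform
Da_Ext	1000000.4	uniform
ATP	1998350.8	uniform
cAMP	35.6	uniform
PDE1	3125.4	uniform
PDE1CamCa4	855.5	uniform
PDE10	800.6	pde10
PDE10cAMP	118.3	pde10
pPDE10	364.3	pde10
pPDE10cAMP	34.0	pde10
AMP	606.0	uniform
CamCa2	341.9	uniform
Cam	4921.5	uniform
PP2BCam	2359.2	uniform
PP2BCamCa2	1218.4	uniform
PP2BCamCa4	8.1	uniform
CaMKII	11318.4	uniform
CaMKIIpCamCa4	140.0	uniform
CaMKIIp	500.0	uniform
CaMKIIpPP1	242.7	uniform
CaMKIIpCamCa4PP1	8.1	uniform
PP1	3750.0	uniform
PP2A_BPR72	800.0	uniform
PP2A_B56d	630.0	uniform
DARPP32	36400.0	uniform
p34DARPP32_PP1	650.0	uniform
p34DARPP32_PP1_PP2A_B56d	11.3	uniform
Cdk5	1088.6	uniform
Cdk5DARPP32	2057.7	uniform
p75DARPP32	10370.9	uniform
p75DARPP32_PP2A_BPR72	200.0	uniform
p75DARPP32_PP2A_B56d	200.0	uniform
p75DARPP32_CaPP2A	25.0	uniform
p75DARPP32_pPP2A	120.0	uniform
pPP2A	140.0	uniform
CaPP2A	33.0	uniform
pmca	2500.0	membrane
ncx	4800.0	membrane
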