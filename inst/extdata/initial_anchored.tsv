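# Anchored pools.  spine_nM is the local concentration when the pool is
# anchored in the spine head (the pka family additionally occupies the PSD
# slice; the accomplex family is excluded from the PSD).  focal_picoSD is the
# printed surface density for dendritic anchoring; it is retained for
# reference only — dendritic (focal) placements re-use the exact spine-derived
# molecule totals so that every anchoring configuration carries identical
# global and local amounts (count parity).
# GluA1 receptors live in the PSD only; their abundance is a package choice
# (receptors per PSD), see the methods vignette.
species	spine_nM	focal_picoSD	family
R	153.9	20.3	accomplex
Gabg	8158.3	1012.5	accomplex
GabgR	1255.5	160.8	accomplex
GaGTP	8.1	0.0	accomplex
GaGDP	90.0	12.0	accomplex
Gbg	43.2	0.0	accomplex
AC	7428.0	887.6	accomplex
ACGaGTPCa_ATP	14.0	0.0	accomplex
ACGaGTP_ATP	114.5	19.0	accomplex
ACCa	2376.0	259.9	accomplex
PKA	7050.0	1130.0	pka
PKAcAMP2	925.0	155.0	pka
PKAcAMP4	137.5	30.0	pka
PKAc	300.0	60.0	pka
PKAr	150.0	30.0	pka
GluA1	100	NA	psd_count
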