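id	name	compartment	role	initial_conc_mM
AA	arachidonic acid	intracellular	metabolite	9.9999999999999997e-29
PGH2	prostaglandin H2	intracellular	metabolite	9.9999999999999997e-29
PGE2	prostaglandin E2	intracellular	metabolite	9.9999999999999997e-29
PGF2a	prostaglandin F2alpha	intracellular	metabolite	9.9999999999999997e-29
PGD2	prostaglandin D2	intracellular	metabolite	9.9999999999999997e-29
PGJ2	prostaglandin J2	intracellular	metabolite	9.9999999999999997e-29
PGJ2_15d	15-deoxy-prostaglandin J2	intracellular	metabolite	9.9999999999999997e-29
PGI2	prostaglandin I2	intracellular	metabolite	9.9999999999999997e-29
PGF1a_6keto	6-keto-prostaglandin F1alpha	intracellular	metabolite	9.9999999999999997e-29
TXA2	thromboxane A2	intracellular	metabolite	9.9999999999999997e-29
TXB2	thromboxane B2	intracellular	metabolite	9.9999999999999997e-29
PGE2_15keto	15-keto-prostaglandin E2	intracellular	metabolite	9.9999999999999997e-29
PGE2_dhk	13,14-dihydro-15-keto-prostaglandin E2	intracellular	metabolite	9.9999999999999997e-29
PGF2a_15keto	15-keto-prostaglandin F2alpha	intracellular	metabolite	9.9999999999999997e-29
PGF2a_dhk	13,14-dihydro-15-keto-prostaglandin F2alpha	intracellular	metabolite	9.9999999999999997e-29
HPETE5	5-hydroperoxy-eicosatetraenoic acid	intracellular	metabolite	9.9999999999999997e-29
HETE5	5-hydroxy-eicosatetraenoic acid	intracellular	metabolite	9.9999999999999997e-29
oxoETE5	5-oxo-eicosatetraenoic acid	intracellular	metabolite	9.9999999999999997e-29
HPETE12	12-hydroperoxy-eicosatetraenoic acid	intracellular	metabolite	9.9999999999999997e-29
HETE12	12-hydroxy-eicosatetraenoic acid	intracellular	metabolite	9.9999999999999997e-29
HPETE15	15-hydroperoxy-eicosatetraenoic acid	intracellular	metabolite	9.9999999999999997e-29
HETE15	15-hydroxy-eicosatetraenoic acid	intracellular	metabolite	9.9999999999999997e-29
LTA4	leukotriene A4	intracellular	metabolite	9.9999999999999997e-29
LTB4	leukotriene B4	intracellular	metabolite	9.9999999999999997e-29
LTC4	leukotriene C4	intracellular	metabolite	9.9999999999999997e-29
AA	extracellular arachidonic acid	extracellular	metabolite	9.9999999999999997e-29
PGH2	extracellular prostaglandin H2	extracellular	metabolite	9.9999999999999997e-29
PGE2	extracellular prostaglandin E2	extracellular	metabolite	9.9999999999999997e-29
PGF2a	extracellular prostaglandin F2alpha	extracellular	metabolite	9.9999999999999997e-29
PGD2	extracellular prostaglandin D2	extracellular	metabolite	9.9999999999999997e-29
PGJ2	extracellular prostaglandin J2	extracellular	metabolite	9.9999999999999997e-29
PGJ2_15d	extracellular 15-deoxy-prostaglandin J2	extracellular	metabolite	9.9999999999999997e-29
PGI2	extracellular prostaglandin I2	extracellular	metabolite	9.9999999999999997e-29
PGF1a_6keto	extracellular 6-keto-prostaglandin F1alpha	extracellular	metabolite	9.9999999999999997e-29
TXA2	extracellular thromboxane A2	extracellular	metabolite	9.9999999999999997e-29
TXB2	extracellular thromboxane B2	extracellular	metabolite	9.9999999999999997e-29
PGE2_15keto	extracellular 15-keto-prostaglandin E2	extracellular	metabolite	9.9999999999999997e-29
PGE2_dhk	extracellular 13,14-dihydro-15-keto-prostaglandin E2	extracellular	metabolite	9.9999999999999997e-29
PGF2a_dhk	extracellular 13,14-dihydro-15-keto-prostaglandin F2alpha	extracellular	metabolite	9.9999999999999997e-29
HPETE5	extracellular 5-hydroperoxy-eicosatetraenoic acid	extracellular	metabolite	9.9999999999999997e-29
HETE5	extracellular 5-hydroxy-eicosatetraenoic acid	extracellular	metabolite	9.9999999999999997e-29
oxoETE5	extracellular 5-oxo-eicosatetraenoic acid	extracellular	metabolite	9.9999999999999997e-29
HPETE12	extracellular 12-hydroperoxy-eicosatetraenoic acid	extracellular	metabolite	9.9999999999999997e-29
HETE12	extracellular 12-hydroxy-eicosatetraenoic acid	extracellular	metabolite	9.9999999999999997e-29
HPETE15	extracellular 15-hydroperoxy-eicosatetraenoic acid	extracellular	metabolite	9.9999999999999997e-29
HETE15	extracellular 15-hydroxy-eicosatetraenoic acid	extracellular	metabolite	9.9999999999999997e-29
LTA4	extracellular leukotriene A4	extracellular	metabolite	9.9999999999999997e-29
LTB4	extracellular leukotriene B4	extracellular	metabolite	9.9999999999999997e-29
LTC4	extracellular leukotriene C4	extracellular	metabolite	9.9999999999999997e-29
PLA2	phospholipase A2	intracellular	enzyme	0.0000000000000000e+00
COX1	cyclooxygenase-1	intracellular	enzyme	0.0000000000000000e+00
COX2	cyclooxygenase-2	intracellular	enzyme	0.0000000000000000e+00
PGES	prostaglandin E synthase	intracellular	enzyme	0.0000000000000000e+00
PGFS	prostaglandin F synthase	intracellular	enzyme	0.0000000000000000e+00
PGDS	prostaglandin D synthase	intracellular	enzyme	0.0000000000000000e+00
PGIS	prostaglandin I synthase	intracellular	enzyme	0.0000000000000000e+00
TXAS	thromboxane A synthase	intracellular	enzyme	0.0000000000000000e+00
PGDH15	15-prostaglandin dehydrogenase	intracellular	enzyme	0.0000000000000000e+00
PTGR2	prostaglandin reductase 2	intracellular	enzyme	0.0000000000000000e+00
LOX5_FLAP	5-lipoxygenase/FLAP complex	intracellular	enzyme	0.0000000000000000e+00
LOX5	5-lipoxygenase	intracellular	enzyme	0.0000000000000000e+00
LOX12	12-lipoxygenase	intracellular	enzyme	0.0000000000000000e+00
LOX15	15-lipoxygenase	intracellular	enzyme	0.0000000000000000e+00
PHGPx	phospholipid hydroperoxide glutathione peroxidase	intracellular	enzyme	0.0000000000000000e+00
HEDH5	5-hydroxyeicosanoid dehydrogenase	intracellular	enzyme	0.0000000000000000e+00
LTA4H	leukotriene A4 hydrolase	intracellular	enzyme	0.0000000000000000e+00
LTC4S	leukotriene C4 synthase	intracellular	enzyme	0.0000000000000000e+00
PGT	prostaglandin transporter	intracellular	transporter	0.0000000000000000e+00
ABC	ATP-binding cassette transporter	intracellular	transporter	0.0000000000000000e+00
AA_src	unspecified arachidonic acid source	intracellular	source	0.0000000000000000e+00
memAA	membrane-bound arachidonic acid pool	intracellular	source	1.0000000000000000e+00
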