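gene	fly_gene	cluster	category
CALM3	Cam	core	none
ATP1B3	nrv3	core	none
YWHAG	14-3-3zeta	core	epilepsy
ATP1A3	Atpalpha	core	epilepsy
SYT1	Syt1	core	epilepsy_related
ALDOA	Aldo	core	none
COX6C	cype	core	none
DNM1	shi	core	epilepsy
CAMK2B	CaMKII	core	epilepsy_related
ENO2	Eno	core	none
NAPB	alphaSnap	core	epilepsy
ATP6V1A	Vha68-1	core	epilepsy
RBMS1	shep	second	none
ELAVL2	fne	second	none
KCNA1/2	Sh	second	epilepsy
SNAP25	Snap25	second	epilepsy_related
STMN2	stai	second	none
RTN1/RTN3	Rtnl1	second	none
NPTN	Bsg	second	none
STXBP1	Rop	second	epilepsy
GUCY1A2	Gycalpha99B	second	none
MAPK8	bsk	second	none
GNB5	Gbeta5	second	epilepsy_related
GPI	Pgi	second	epilepsy_related
NDUFB11	NP15.6	second	epilepsy_related
LIN7B	veli	second	none
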