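alias	id
IL-1beta	IL1B
IL-1b	IL1B
TNF-alpha	TNFA
TNFa	TNFA
IL-6	IL6
IL-8	IL8
IL-17	IL17
IL-18	IL18
IFN-gamma	IFNG
TGF-beta	TGFB
TGFb	TGFB
FGF-2	FGF2
BMP-2	BMP2
IGF-1	IGF1
IGF1	IGF1
IL-4	IL4
IL-10	IL10
IL-13	IL13
MMP-1	MMP1
MMP-3	MMP3
MMP-13	MMP13
ADAMTS4	ADAMTS
ADAMTs	ADAMTS
TIMP-1	TIMP
COL2A1	COL2A
aggrecan	ACAN
VEGFA	VEGF
PGE-2	PGE2
PEG2	PGE2
nitric oxide	NO
reactive oxygen species	ROS
cytochrome c	CYCS
caspase 8	CASP8
LIF	LIF
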