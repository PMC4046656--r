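pattern	family	priority
MADS|\bAGAMOUS\b|\bAGL[0-9]|\bTAGL?[0-9]|SEPALLATA|\bSVP\b	MADS-box	1
\bWRKY	WRKY	2
\bNAC\b|\bANAC[0-9]	NAC	3
\bAP2\b|\bERF[0-9]?\b|ethylene[- ]responsive	AP2/ERF	4
heat[- ]shock (transcription )?factor|\bHSF	HSF	5
\bGRAS\b|scarecrow|\bSCL[0-9]	GRAS	6
Aux/IAA|\bIAA[0-9]|auxin[- ]induced protein	Aux/IAA	7
CAMTA|calmodulin[- ]binding transcription	CAMTA	8
GAGA[- ]binding	GAGA-binding	9
\bEIN3|\bEIL[0-9]?\b	EIN3/EIL	10
\bE2F	E2F/DP	11
CCAAT	CCAAT-binding	12
\bC2H2	C2H2L	13
bZIP|basic leucine zipper|\bHY5\b|\bRF2[ab]\b|\bTGA[0-9]|\bVIP1\b	bZIP	14
bHLH|basic helix[- ]loop[- ]helix|\bMYC[0-9]?\b	bHLH	15
\bMYB	MYB	16
homeobox|homeodomain|\bHB-?[0-9]|knotted	homeobox	17
SBP[- ]box|squamosa promoter	SBP-box	18
\bTCP[0-9]?\b	TCP	19
zinc[- ]finger|\bZF\b|RING[- ]H2	ZF	20
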