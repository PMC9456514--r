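# PEP subunit membership registry, v1.
# canonical	role	aliases (';'-separated; matching is case-insensitive,
# whitespace-stripped, and tolerant of a leading species prefix "Sa")
canonical	role	aliases
rpoA	core	alpha;RpoA;SaRpoA
rpoB	core	beta;RpoB;SaRpoB
rpoC1	core	beta';RpoC1;SaRpoC1
rpoC2	core	beta'';RpoC2;SaRpoC2
PAP1	pap	pTAC3;TAC3;PAP1/pTac3
PAP2	pap	pTAC2;TAC2;PAP2/pTac2
PAP3	pap	pTAC10
PAP4	pap	FSD3
PAP5	pap	pTAC12;HEMERA;HMR;PAP5/PTAC12
PAP6	pap	FLN1;PAP6/FLN1
PAP7	pap	pTAC14
PAP8	pap	pTAC6
PAP9	pap	FSD2
PAP10	pap	TrxZ;TRX-Z
PAP11	pap	MurE;MURE;MurE-like
PAP12	pap	pTAC7
FLN2	candidate	FLN-2
pTAC18	candidate	TAC18
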