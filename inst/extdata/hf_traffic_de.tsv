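protein	module	traffic	t	p	known_biomarker
FN1	7	140037.9	-0.99	NS	FALSE
PDGFRB	16	118789.9	0.62	NS	FALSE
ITGB1	13	107208.2	-0.44	NS	FALSE
C3	1	53979.1	1.12	NS	FALSE
COL1A1	7	48837.3	1.43	NS	FALSE
TGFB1	6	45861.8	-1.98	0.06	FALSE
MMP2	9	43355.8	0.16	NS	TRUE
PTEN	17	43018.0	-2.45	0.02	FALSE
CHGB	17	42398.0	0.27	NS	TRUE
ITGB3	7	41256.5	NA	NA	FALSE
ADAM15	16	36080.8	-0.21	NS	FALSE
IL6ST	16	35295.1	NA	NA	FALSE
COL2A1	7	33618.7	NA	NA	TRUE
TNFSF11	9	32703.6	NA	NA	TRUE
ITGAV	9	31291.3	NA	NA	FALSE
PDGFRA	16	31130.0	-0.65	NS	FALSE
LRP1	9	30483.8	-0.37	NS	FALSE
SRC	16	28672.6	-0.54	NS	FALSE
MMP9	9	27463.8	-1.15	NS	TRUE
TNF	12	27462.7	1.39	NS	TRUE
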