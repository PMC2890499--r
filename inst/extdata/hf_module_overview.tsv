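module	n_proteins	n_interactions	median_traffic	n_imi	top_bp	top_cc
1	33	87	64	2	innate immune response	extracellular region part
2	17	57	32	3	immune response	cell part
3	21	84	40	12	cell adhesion	extracellular matrix part
4	33	84	64	7	circulation	plasma membrane
5	32	94	62	7	coagulation	extracellular region part
6	37	117	72	4	tissue remodeling	integral to plasma membrane
7	133	731	264	46	cell adhesion	extracellular region part
8	11	26	20	1	taxis	plasma membrane part
9	100	469	198	31	protein digestion	extracellular region part
10	24	64	46	7	positive regulation of signal transduction	NA
11	19	54	36	8	proteolysis	endoplasmic reticulum
12	51	182	100	8	immune response	extracellular space
13	68	212	134	14	cell adhesion	receptor complex
14	7	21	12	3	cell adhesion	NA
15	18	42	34	4	muscle contraction	myofibril
16	112	390	222	9	cell communication	cytoplasm
17	30	91	58	1	response to stress	DNA-directed RNA polymerase complex
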