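# Published sugar beet repeat-content proportions: RefBeet 1.1 assembly annotation (567 Mb) vs read-clustering estimate (758 Mb genome), percent of the respective genome size.
repeat	assembly_pct	cluster_pct
Ty3-gypsy retrotransposons	7.61	4.37
Beetle2	0.12	0.48
Beetle4	0.00	0.10
Beetle7	0.08	0.65
Total Beetle	0.50	1.25
Bongo3	2.02	1.90
Ty1-copia retrotransposons	4.56	4.99
Cotzilla	1.72	3.02
Salire	0.34	0.49
Patty	0.18	0.10
ENV-like retrotransposons	4.05	2.14
Elbe family	3.01	2.03
LINE	3.77	0.14
Tandem Repeat	3.31	11.15
pBV	0.27	6.17
pEV	0.17	3.58
Niobe	0.02	0.06
BvSat04	0.03	0.03
DNA transposons	2.07	3.93
Mutator	0.00	2.01
En/Spm	0.00	0.89
Helitron	0.56	0.10
SINE	0.49	0.05
rDNA	0.15	1.56
Pararetrovirus	0.06	0.09
Unclassified Dispersed Repeats	0.08	0.00
plastid DNA	0.00	9.58
Unknown	6.28	4.69
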