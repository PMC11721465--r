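variant	ligand	KD	KD_unit	fold_printed	class
WT	apoE4	281	nM		binding
R47H	apoE4	643	nM	2.29	binding
R62H	apoE4	561	nM	2.00	binding
D87N	apoE4	25	nM	11.24	binding
T96K	apoE4	891	nM	3.17	binding
M41D	apoE4	1426	nM	5.07	binding
W44D	apoE4	2565	nM	9.12	binding
L69D	apoE4	55060	nM	195.94	binding
W70D	apoE4	28110	nM	100.04	binding
F74D	apoE4	9709	nM	34.55	binding
L69D/L71D	apoE4	NA	nM		no_binding_detected
W44D/L69D/L71D	apoE4	NA	nM		no_binding_detected
R76D	apoE4	1529	nM	5.44	binding
R77D	apoE4	1659	nM	5.90	binding
R46A/R47A	apoE4	388	nM	1.38	binding
R122D/K123D	apoE4	120	nM	2.30	binding
WT	C1q	0.65	uM		binding
M41D	C1q	2.54	uM		binding
L69D	C1q	NA	uM		decreased_binding
W70D	C1q	NA	uM		decreased_binding
L71D	C1q	0.058	uM		binding
F74D	C1q	0.11	uM		binding
L89D	C1q	NA	uM		decreased_binding
L69D/L71D	C1q	NA	uM		binding_not_fit
W44D/L69D/L71D	C1q	NA	uM		binding_not_fit
R46A/R47A	C1q	NA	uM		no_binding_detected
R46A	C1q	NA	uM		no_binding_detected
R46D	C1q	NA	uM		no_binding_detected
R47H	C1q	0.18	uM		binding
R62H	C1q	1.66	uM		binding
R76D	C1q	13.8	uM		binding
R77D	C1q	NA	uM		no_binding_detected
T96K	C1q	NA	uM		no_binding_detected
L75D	C1q	0.11	uM		binding
T85D	C1q	0.11	uM		binding
R122D/K123D	C1q	0.82	uM		binding
WT	IL-34	16.5	nM		binding
R47H	IL-34	79.8	nM	4.8	binding
R62H	IL-34	75	nM	4.5	binding
D87N	IL-34	28.4	nM	1.7	binding
T96K	IL-34	23.7	nM	1.4	binding
R46D	IL-34	18.0	nM	1.1	binding
R76D	IL-34	NA	nM		no_binding_detected
R77D	IL-34	114	nM	6.9	binding
L75D	IL-34	36.6	nM	2.2	binding
W78D	IL-34	17.2	nM	1.04	binding
T85D	IL-34	21.5	nM	1.3	binding
R122E	IL-34	29.4	nM	1.8	binding
R122D/K123D	IL-34	18.5	nM	1.1	binding
L69D/L71D	IL-34	20.2	nM	1.2	binding
W44D/L69D/L71D	IL-34	25.8	nM	1.6	binding
WT	TDP-43	NA	nM		binding
R46A/R47A	TDP-43	NA	nM		decreased_binding
W70D	TDP-43	NA	nM		no_binding_detected
L69D/L71D	TDP-43	NA	nM		no_binding_detected
W44D/L69D/L71D	TDP-43	NA	nM		no_binding_detected
R47H	TDP-43	NA	nM		binding
R62H	TDP-43	NA	nM		binding
D87N	TDP-43	NA	nM		binding
R122D/K123D	TDP-43	NA	nM		binding
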