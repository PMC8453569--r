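trait	n	mean	sd	cv_pct	min	max
MY	5446	1367	532	38.92	100	3924
F_PCT	5437	7.08	1.06	14.97	2.53	15.78
FY	5437	94.80	33.91	35.77	6	277
P_PCT	5436	5.82	0.65	11.17	2.32	11.60
PY	5436	78.93	29.32	37.15	6	239
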