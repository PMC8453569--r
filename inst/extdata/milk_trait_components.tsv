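trait	var_u	var_pu	var_pw	var_h	var_p	h2	h2_se	r_acr	r_acr_se	r_wit	r_wit_se	ftd2	ftd2_se
MY	24811	16967	52716	96410	254968	0.10	0.03	0.16	0.02	0.37	0.03	0.38	0.03
F_PCT	0.1276	0.0734	0.0620	0.4530	1.1201	0.11	0.03	0.18	0.03	0.23	0.03	0.40	0.03
FY	103	66	244	369	1070	0.06	0.03	0.16	0.02	0.39	0.03	0.34	0.03
P_PCT	0.0588	0.0306	0.0257	0.1269	0.3786	0.15	0.03	0.24	0.02	0.30	0.03	0.33	0.03
PY	71	44	168	333	805	0.09	0.03	0.14	0.02	0.35	0.03	0.41	0.03
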