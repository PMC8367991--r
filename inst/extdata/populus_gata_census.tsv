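species	A	n_tf	B	n_tf_as	genome_genes
P_trichocarpa	39	67	13	41	42950
P_pruinosa	37	37	0	0	35131
P_euphratica	40	55	9	24	30688
P_deltoides	38	55	7	24	44853
P_tremuloides	37	44	7	14	36830
P_tremula	33	60	16	43	35309
P_tremula_x_alba	38	71	16	49	41335
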