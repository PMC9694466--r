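system	dE_vdW	dE_elec	dE_covalent	dG_solv	dE_bind	minus_TdS	dG_cal	ddG_cal	dG_exp	ic50_nM
G12C	-71.53	-306.89	89.99	211.95	-76.48	37.67	-38.81	NA	-12.75	1.01
G12C-R68S	-62.38	-299.89	89.71	204.29	-68.28	36.94	-31.34	7.47	-9.68	147.07
G12C-K16T	-63.40	-319.38	90.35	226.33	-66.10	36.84	-29.26	9.55	-9.27	289.47
G12C-Y96C	-62.05	-281.80	89.67	187.00	-67.18	36.45	-30.73	8.08	-9.18	332.90
G12C-Y96D	-56.34	-308.99	89.64	215.42	-60.39	34.81	-28.18	10.63	-9.10	376.64
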