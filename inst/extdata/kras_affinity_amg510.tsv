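system	dE_vdW	dE_elec	dE_covalent	dG_solv	dE_bind	minus_TdS	dG_cal	ddG_cal	dG_exp	ic50_nM
G12C	-62.48	-152.11	89.06	59.13	-67.39	35.96	-31.43	NA	-10.91	19.81
G12C-R68S	-51.83	-147.85	89.12	52.20	-58.36	35.78	-22.58	8.85	-8.78	643.27
G12C-K16T	-58.18	-146.96	89.83	55.93	-59.38	35.84	-23.54	7.89	-7.93	2524
G12C-Y96C	-56.68	-148.16	88.94	54.48	-61.42	35.54	-25.88	5.55	-7.68	3814
G12C-Y96D	-52.55	-145.39	89.32	52.01	-56.59	35.19	-21.40	10.03	-7.31	6920.67
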