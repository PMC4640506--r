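feature_id	cpm_fed	cpm_starved	log2fc	p_value	fdr	fold_change
cel-miR-39-3p	49.9	1008.5	4.3	6.9e-09	9.4e-07	20.2
cel-miR-37-3p	38.2	768	4.3	7.5e-09	9.4e-07	20.1
cel-miR-35-3p	230.1	4053.5	4.1	2.4e-08	2.0e-06	17.6
cel-miR-38-3p	41.3	636.1	3.9	8.4e-08	5.3e-06	15.4
cel-miR-41-3p	1.7	25.8	4.0	2.5e-07	1.3e-05	15.4
cel-let-7-3p	13.9	1.1	-3.7	1.7e-06	7.0e-05	-13.0
cel-miR-36-3p	133.3	1356.2	3.4	2.9e-06	1.0e-04	10.2
cel-miR-4813-5p	0.8	9.5	3.6	4.8e-06	1.5e-04	12.4
cel-miR-40-3p	34.3	296.4	3.1	1.2e-05	3.3e-04	8.6
cel-mir-85	2.2	0.1	-4.4	3.6e-05	9.1e-04	-20.6
cel-miR-34-3p	0.4	3.9	3.1	1.8e-04	4.1e-03	8.6
cel-miR-41-5p	2.4	15.5	2.7	2.3e-04	4.7e-03	6.4
cel-mir-35	0	1.2	4.6	4.9e-04	9.5e-03	24.0
cel-miR-359	2.6	13.9	2.4	8.2e-04	1.5e-02	5.3
cel-miR-85-5p	2.4	0.3	-3.0	1.3e-03	2.1e-02	-7.9
cel-miR-39-5p	2.1	10	2.2	1.9e-03	3.0e-02	4.7
cel-miR-240-5p	687.2	2784.7	2.0	2.9e-03	4.3e-02	4.1
cel-miR-246-3p	665.3	2646.1	2.0	3.3e-03	4.6e-02	4.0
cel-mir-79	1.0	0.1	-3.3	3.6e-03	4.8e-02	-9.7
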