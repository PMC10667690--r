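group	trait	minimum	mean	maximum
anaerobic_exp1	germ14_pct	0.0	29.2	86.0
anaerobic_exp1	germ21_pct	0.4	59.8	100.0
anaerobic_exp1	height14	7.5	13.4	27.0
anaerobic_exp1	height21	9.6	28.3	38.0
anaerobic_exp1	culm	1.1	1.4	1.6
anaerobic_exp1	rootlen	2.4	5.3	9.6
anaerobic_exp1	shootdm	0.003	0.019	0.034
anaerobic_exp1	rootdm	0.001	0.005	0.012
anaerobic_exp2	germ14_pct	0.0	31.1	87.7
anaerobic_exp2	germ21_pct	0.0	47.5	93.7
anaerobic_exp2	height14	8.5	17.6	32.8
anaerobic_exp2	height21	18.4	36.5	49.2
anaerobic_exp2	culm	1.1	1.9	2.5
anaerobic_exp2	rootlen	1.2	7.7	13.1
anaerobic_exp2	shootdm	0.004	0.030	0.057
anaerobic_exp2	rootdm	0.000	0.007	0.018
aerobic_exp1	germ14_pct	38.3	98.2	100.0
aerobic_exp1	germ21_pct	38.3	98.2	100.0
aerobic_exp1	height14	14.3	25.9	36.0
aerobic_exp1	height21	23.1	38.5	52.0
aerobic_exp1	culm	1.6	2.0	2.2
aerobic_exp1	rootlen	4.5	8.7	14.1
aerobic_exp1	shootdm	0.004	0.030	0.057
aerobic_exp1	rootdm	0.003	0.012	0.022
aerobic_exp2	germ14_pct	54.4	98.1	100.0
aerobic_exp2	germ21_pct	60.8	98.4	100.0
aerobic_exp2	height14	19.8	31.6	42.3
aerobic_exp2	height21	31.1	49.7	63.1
aerobic_exp2	culm	2.0	3.4	4.7
aerobic_exp2	rootlen	4.3	9.3	14.9
aerobic_exp2	shootdm	0.026	0.092	0.153
aerobic_exp2	rootdm	0.007	0.016	0.029
anaerobic_across	germ14_pct	0.0	29.4	72.4
anaerobic_across	germ21_pct	14.4	53.7	85.9
anaerobic_across	height14	12.6	15.6	21.8
anaerobic_across	height21	19.9	32.4	40.2
anaerobic_across	culm	1.6	1.7	1.7
anaerobic_across	rootlen	5.7	6.5	7.6
anaerobic_across	shootdm	0.015	0.025	0.036
anaerobic_across	rootdm	0.003	0.007	0.013
aerobic_across	germ14_pct	53.1	98.3	100.0
aerobic_across	germ21_pct	54.5	98.4	100.0
aerobic_across	height14	18.3	28.8	37.0
aerobic_across	height21	30.3	44.1	54.8
aerobic_across	culm	2.5	2.7	2.8
aerobic_across	rootlen	8.3	9.0	9.6
aerobic_across	shootdm	0.042	0.071	0.102
aerobic_across	rootdm	0.008	0.014	0.020
overall_across	germ14_pct	30.8	63.9	79.7
overall_across	germ21_pct	39.4	76.1	85.9
overall_across	height14	12.5	21.9	30.1
overall_across	height21	25.7	38.2	47.6
overall_across	culm	2.0	2.2	2.3
overall_across	rootlen	6.6	7.8	9.0
overall_across	shootdm	0.028	0.048	0.068
overall_across	rootdm	0.006	0.010	0.016
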