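metric	direction	raw_dorado	raw_f5c_resquiggle	raw_f5c_eventalign	raw_uncalled4	raw_dynamont	score_dorado	score_f5c_resquiggle	score_f5c_eventalign	score_uncalled4	score_dynamont
median_delta	higher	15.5	59.0	60.5	61.0	64.5	0.240	0.915	0.938	0.946	1.000
mad_delta	higher	6.0	5.5	5.5	6.0	8.0	0.750	0.688	0.688	0.750	1.000
homogeneity	lower	16.0	12.5	12.5	13.0	14.5	0.000	0.219	0.219	0.188	0.094
segmented_reads	higher	10088	9245	8884	9329	10088	1.000	0.916	0.881	0.925	1.000
truncated_reads	lower	0	9245	8865	9005	3124	1.000	0.000	0.041	0.026	0.662
min_read_length	lower	5	201	75	67	6	0.975	0.000	0.627	0.667	0.970
n50_read_length	higher	1550	1483	1391	1445	1546	1.000	0.957	0.897	0.932	0.997
max_read_length	higher	111593	41777	9609	10027	111594	1.000	0.374	0.086	0.090	1.000
flye_total_length	higher	100285	94190	79174	98534	93379	1.000	0.939	0.789	0.983	0.931
flye_n50	higher	2786	2732	2819	2860	2797	0.974	0.955	0.986	1.000	0.978
flye_mean_coverage	higher	7.6	7.5	4.3	4.2	7.6	1.000	0.980	0.565	0.549	0.993
svim_structural_variants	higher	4	0	0	0	0	1.000	0.000	0.000	0.000	0.000
am_score	higher	NA	NA	NA	NA	NA	9.94	6.94	6.72	7.05	9.63
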