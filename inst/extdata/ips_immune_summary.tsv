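# Immune parameters of 38 glioma patients stratified by current dexamethasone use
# (19 exposed / 19 unexposed); published per-group summary statistics.
# printed_p is the p-value as printed in the source table ("<0.0001" coded as 0.0001 with printed_lt = TRUE).
variable	mean_exposed	sd_exposed	n_exposed	mean_unexposed	sd_unexposed	n_unexposed	printed_p	printed_lt
age_at_surgery_yrs	54.8	17.43	19	47.84	13.28	19	0.18	FALSE
ndmi_score	2.36	1.55	19	-1.73	1.14	19	0.0001	TRUE
abs_b_cells	310.4	215.7	19	281.4	123.9	19	0.62	FALSE
abs_cd4	517.6	443.8	19	930.5	466.9	19	0.008	FALSE
abs_cd8	374	223.1	19	468.1	230.1	19	0.21	FALSE
abs_monocytes	536.7	357.2	19	489.2	140.2	19	0.59	FALSE
abs_nk	246.8	129.5	19	393.6	204.3	19	0.01	FALSE
abs_neutrophils	8651.2	4527	19	4180	2369.1	19	0.0007	FALSE
mmdsc_cd16neg	95.9	84.7	19	24.5	28.8	19	0.002	FALSE
mmdsc_cd16pos	28.6	31.1	19	13.1	27.3	19	0.11	FALSE
mmdsc_pct_monocytes	22.1	15.4	19	8.7	8.3	19	0.002	FALSE
mmdsc_counts	124.4	112.1	19	37.7	55.3	19	0.005	FALSE
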