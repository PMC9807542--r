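variant_id	effect_allele	weight	is_hla	eaf
rs2476601	A	0.80	FALSE	0.10
rs689	T	0.65	FALSE	0.70
rs2292239	T	0.30	FALSE	0.34
rs3184504	T	0.28	FALSE	0.47
rs1893217	G	0.27	FALSE	0.16
rs12251307	T	0.25	FALSE	0.10
rs6679677	A	0.24	FALSE	0.10
rs10509540	C	0.23	FALSE	0.28
rs4948088	A	0.22	FALSE	0.03
rs7804356	C	0.20	FALSE	0.23
rs11594656	T	0.19	FALSE	0.73
rs12708716	A	0.18	FALSE	0.65
rs2104286	A	0.18	FALSE	0.72
rs10517086	A	0.17	FALSE	0.28
rs4505848	G	0.16	FALSE	0.35
rs7202877	T	0.16	FALSE	0.93
rs2290400	T	0.15	FALSE	0.44
rs3825932	C	0.14	FALSE	0.72
rs1465788	C	0.14	FALSE	0.70
rs2281808	C	0.13	FALSE	0.65
rs9976767	G	0.13	FALSE	0.43
rs4788084	C	0.12	FALSE	0.58
rs7574865	T	0.12	FALSE	0.22
rs11711054	G	0.11	FALSE	0.34
rs1990760	T	0.10	FALSE	0.60
rs5753037	T	0.10	FALSE	0.41
rs7111341	T	0.08	FALSE	0.27
rs9268645	G	0.60	TRUE	0.30
rs7454108	C	0.55	TRUE	0.12
rs2187668	T	0.50	TRUE	0.13
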