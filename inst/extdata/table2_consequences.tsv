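gene_id	variant_id	consequence_class	sift_score
Gpt	v01	deleterious_domain_missense	0.01
Gpt	v02	utr	NA
Gpt	v03	promoter	NA
Gpt	v04	ctcf_binding	NA
Gpt	v05	splice_site	NA
Cbx6	v06	deleterious_domain_missense	0.02
Cbx6	v07	utr	NA
Cbx6	v08	promoter	NA
Cbx6	v09	ctcf_binding	NA
Cbx6	v10	splice_site	NA
Apol6	v11	deleterious_domain_missense	0.03
Apol6	v12	utr	NA
Apol6	v13	enhancer	NA
Apol6	v14	ctcf_binding	NA
Apol6	v15	splice_site	NA
Apol8	v16	deleterious_domain_missense	0.04
Apol8	v17	utr	NA
Apol8	v18	promoter	NA
Apol8	v19	splice_site	NA
Trap1	v20	tolerated_domain_missense	0.40
Rrn3	v21	tolerated_domain_missense	0.31
Mapk1	v22	utr	NA
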