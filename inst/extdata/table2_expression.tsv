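gene_id	tissue	fold_change	p_value
Gpt	gonadal_adipose	0.810	1.2e-07
Gpt	liver	0.965	2.8e-06
Apol6	gonadal_adipose	0.847	3.9e-06
Apol6	liver	0.989	0.503
Apol8	gonadal_adipose	0.990	0.531
Apol8	liver	1.002	0.887
Trap1	gonadal_adipose	0.959	5.5e-05
Trap1	liver	0.995	0.426
Rrn3	gonadal_adipose	0.943	2.0e-06
Rrn3	liver	0.917	1.3e-06
Mapk1	gonadal_adipose	1.014	4.7e-02
Mapk1	liver	0.999	0.924
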