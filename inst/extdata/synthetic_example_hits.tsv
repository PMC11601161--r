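query_id	target_id	evalue
d1qmha1	t01	0.0005
d1qmha1	t02	0.002
d1qmha1	t03	0.01
d1qmha1	t04	0.03
d1qmha1	t05	0.07
d1jjcb4	t06	0.001
d1jjcb4	t07	0.004
d1jjcb4	t08	0.02
d1jjcb4	t09	0.05
d1jjcb4	t10	0.08
d1wx1a	t11	0.003
d1wx1a	t12	0.015
d1wx1a	t13	0.04
d1wx1a	t14	0.06
d1wx1a	t15	0.09
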