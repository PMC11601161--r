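id	family
d1qmha1	c.47
d1jjcb4	d.58
d1wx1a	c.39
t01	c.47
t02	c.47
t03	c.47
t04	b.1
t05	a.4
t06	d.58
t07	g.3
t08	d.58
t09	d.58
t10	c.2
t11	c.39
t12	c.39
t13	a.7
t14	b.40
t15	d.15
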