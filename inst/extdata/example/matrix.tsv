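root_id	kxa_n1	kxa_n2	kxa_a1	tuu_t1	tuu_x1	kk_nama	kk_naro	kk_khwe
r01	0	0	0	1	1	1	1	0
r02	0	0	1	0	0	0	1	1
r03	0	0	1	1	0	0	0	0
r04	1	0	0	0	1	0	0	0
r05	1	1	1	0	0	0	1	0
r06	1	1	1	0	0	0	0	0
r07	0	0	0	1	1	0	0	0
r08	0	0	0	0	0	1	1	1
r09	0	0	0	0	0	0	0	1
r10	0	1	0	0	0	0	0	1
r11	0	0	0	1	1	0	0	0
r12	0	0	1	1	0	0	1	0
r13	1	?	1	0	0	0	0	0
r14	0	0	0	0	0	1	0	1
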