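id	name	family	subgroup	cluster_id	latitude	longitude	subsistence	source
kxa_n1	Northern !Xun A	KXA	!Xun	KXA_north	-17.9	19.8	forager	example
kxa_n2	Northern !Xun B	KXA	!Xun	KXA_north	-18.5	21.0	forager	example
kxa_a1	ǂ'Amkoe	KXA	ǂ'Amkoe	KXA_amkoe	-22.0	22.5	forager	example
tuu_t1	Taa East	TUU	Taa	TUU_taa	-23.5	21.5	forager	example
tuu_x1	ǀXam	TUU	!Ui	TUU_ui	-26.3	20.6	forager	example
kk_nama	Nama	KHOE_KWADI	Khoekhoe	KK_khoekhoe	-24.5	17.0	herder	example
kk_naro	Naro	KHOE_KWADI	Kalahari Khoe	KK_naro	-22.3	20.5	forager	example
kk_khwe	Khwe	KHOE_KWADI	Kalahari Khoe	KK_khwe	-18.2	21.8	forager	example
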