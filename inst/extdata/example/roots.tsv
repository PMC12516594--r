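id	primary_meaning	polysemy_meanings	bantu_flag	complex_flag	origin	resolution_level
r01	m01	NA	FALSE	FALSE	KHOE_KWADI	Proto-Khoekhoe
r02	m02	NA	FALSE	FALSE	KHOE_KWADI	Proto-Khoe
r03	m03	NA	FALSE	FALSE	UNIDENTIFIED	NA
r04	m04	NA	FALSE	FALSE	UNIDENTIFIED	NA
r05	m05	m06	FALSE	FALSE	KXA	Proto-Kx'a
r06	m07	NA	FALSE	FALSE	KXA	NA
r07	m05	NA	FALSE	FALSE	TUU	NA
r08	m07	NA	FALSE	FALSE	KHOE_KWADI	NA
r09	m08	NA	FALSE	FALSE	KHOE_KWADI	NA
r10	m09	NA	TRUE	FALSE	UNANNOTATED	NA
r11	m10	NA	FALSE	TRUE	TUU	NA
r12	m11	NA	FALSE	FALSE	TUU	Proto-Taa
r13	m12	NA	FALSE	FALSE	KXA	NA
r14	m13	NA	FALSE	FALSE	KHOE_KWADI	NA
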