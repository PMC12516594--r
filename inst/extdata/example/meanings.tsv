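id	gloss	swadesh200
m01	sheep	FALSE
m02	to milk	FALSE
m03	eland	FALSE
m04	moon	TRUE
m05	fire	TRUE
m06	smoke	TRUE
m07	water	TRUE
m08	springhare	FALSE
m09	maize	FALSE
m10	rib	TRUE
m11	ostrich	FALSE
m12	heart	TRUE
m13	duiker	FALSE
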