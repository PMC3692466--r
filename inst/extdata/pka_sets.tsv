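set	site	role	pka
bjellqvist	nterm	basic	7.50
bjellqvist	cterm	acidic	3.55
bjellqvist	D	acidic	4.05
bjellqvist	E	acidic	4.45
bjellqvist	C	acidic	9.00
bjellqvist	Y	acidic	10.00
bjellqvist	H	basic	5.98
bjellqvist	K	basic	10.00
bjellqvist	R	basic	12.00
emboss	nterm	basic	8.60
emboss	cterm	acidic	3.60
emboss	D	acidic	3.90
emboss	E	acidic	4.10
emboss	C	acidic	8.50
emboss	Y	acidic	10.10
emboss	H	basic	6.50
emboss	K	basic	10.80
emboss	R	basic	12.50
lehninger	nterm	basic	8.00
lehninger	cterm	acidic	3.10
lehninger	D	acidic	3.65
lehninger	E	acidic	4.25
lehninger	C	acidic	8.18
lehninger	Y	acidic	10.07
lehninger	H	basic	6.00
lehninger	K	basic	10.53
lehninger	R	basic	12.48
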