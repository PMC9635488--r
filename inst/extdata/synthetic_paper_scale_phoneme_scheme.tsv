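group	symbol	constituents
onset	p	
onset	b	
onset	t	
onset	d	
onset	k	
onset	g	
onset	f	
onset	v	
onset	s	
onset	z	
onset	S	
onset	Z	
onset	tS	
onset	dZ	
onset	h	
onset	m	
onset	n	
onset	l	
onset	r	
onset	w	
onset	j	
onset	T	
onset	D	
vowel	i	
vowel	I	
vowel	e	
vowel	E	
vowel	a	
vowel	A	
vowel	o	
vowel	O	
vowel	u	
vowel	U	
vowel	@	
vowel	aI	
vowel	aU	
vowel	oI	
coda	p	
coda	b	
coda	t	
coda	d	
coda	k	
coda	g	
coda	f	
coda	v	
coda	s	
coda	z	
coda	S	
coda	Z	
coda	m	
coda	n	
coda	N	
coda	l	
coda	r	
coda	T	
coda	D	
coda	tS	
coda	dZ	
coda	ps	p+s
coda	ks	k+s
coda	ts	t+s
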