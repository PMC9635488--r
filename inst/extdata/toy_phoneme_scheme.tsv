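group	symbol	constituents
onset	b	
onset	k	
onset	h	
onset	p	
onset	t	
onset	C	
onset	f	
vowel	a	
vowel	e	
vowel	i	
vowel	E	
coda	n	
coda	s	
coda	t	
coda	p	
coda	ps	p+s
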