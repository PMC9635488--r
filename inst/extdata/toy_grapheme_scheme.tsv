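group	symbol	constituents
onset	b	
onset	c	
onset	h	
onset	p	
onset	t	
onset	ch	
onset	ph	
vowel	a	
vowel	e	
vowel	i	
vowel	ea	
coda	n	
coda	s	
coda	t	
coda	p	
coda	ps	
coda	st	
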