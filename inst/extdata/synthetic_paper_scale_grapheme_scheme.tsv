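group	symbol	constituents
onset	b	
onset	c	
onset	d	
onset	f	
onset	g	
onset	h	
onset	j	
onset	k	
onset	l	
onset	m	
onset	n	
onset	p	
onset	q	
onset	r	
onset	s	
onset	t	
onset	v	
onset	w	
onset	x	
onset	y	
onset	z	
onset	ch	
onset	ph	
onset	sh	
onset	th	
onset	wh	
onset	qu	
onset	kn	
onset	wr	
onset	gn	
vowel	a	
vowel	e	
vowel	i	
vowel	o	
vowel	u	
vowel	y	
vowel	ai	
vowel	ay	
vowel	au	
vowel	aw	
vowel	ea	
vowel	ee	
vowel	ei	
vowel	ew	
vowel	ey	
vowel	ie	
vowel	oa	
vowel	oe	
vowel	oi	
vowel	oo	
vowel	ou	
vowel	ow	
vowel	oy	
vowel	ue	
vowel	ui	
vowel	igh	
vowel	eigh	
coda	b	
coda	c	
coda	d	
coda	f	
coda	g	
coda	h	
coda	k	
coda	l	
coda	m	
coda	n	
coda	p	
coda	r	
coda	s	
coda	t	
coda	v	
coda	w	
coda	x	
coda	y	
coda	z	
coda	ch	
coda	ck	
coda	ff	
coda	gh	
coda	ll	
coda	ng	
coda	nk	
coda	ph	
coda	sh	
coda	ss	
coda	th	
coda	tch	
coda	zz	
coda	mb	
coda	mn	
coda	ps	
coda	ts	
coda	ks	
coda	lk	
coda	lm	
coda	nd	
coda	nt	
coda	st	
coda	sk	
coda	sp	
coda	ld	
coda	rd	
coda	rn	
coda	rt	
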