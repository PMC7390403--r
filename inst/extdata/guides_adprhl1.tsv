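name	spacer	pam	direction
tyra-T	GGGTCGATGATAGAGAGGAC	TGG	forward
tyrb-T	GGCCCGTAGCAGAGCTGGTG	AGG	reverse
gAdprhl1-e3-1S	GGGATGAGATACTGGAAACC	AGG	forward
gAdprhl1-e3-1L	GGGATGAAATACTGGAAACC	AGG	forward
gAdprhl1-e4-1	GGGCCGTGCACAGGGACCCA	AGG	reverse
gAdprhl1-e6-1	GAGGGAAGAGGGGGAAGAAG	AGG	forward
gAdprhl1-e6-1Mis1	GAGGGAAGAGGGGGAACAAG	AGG	forward
gAdprhl1-e6-1Mis2	GAGGGAAGAGGGGGAACTAG	AGG	forward
gAdprhl1-e1-1	GGCAAGAAGAGCTAAAACAACT	TGG	forward
gAdprhl1-e1-2	GGTGAGACTAGTGATTCCGCTG	TGG	reverse
gAdprhl1-e2-1	GGCACACCCCATTCAATGAAAA	AGG	forward
gAdprhl1-i2-1L	GGAAAGCACTTAGTGACCAG	TGG	reverse
gAdprhl1-i2-2L	GGGAATGTAATAAAAATTAG	TGG	reverse
gAdprhl1-e4-2S	GGAGAAACCACTTGCTCAGTG	GGG	forward
gAdprhl1-e4-2L	GGAAAAACCACTTGTTCAGTG	GGG	forward
gAdprhl1-e4-3S	GGAAGAAGACTATACGGCACA	TGG	forward
gAdprhl1-e4-3L	GGAAGAAGACTATTCGGCACA	TGG	forward
gAdprhl1-e5-1S	GGTTTTATTTTGAAGCCAAG	TGG	forward
gAdprhl1-e5-1L	GGTTTTATTTTGAAACCAAG	TGG	forward
gAdprhl1-e7-1S	GCAGGAGAAGGTGGTGCCAC	TGG	forward
gAdprhl1-e7-1L	GCAGGAGAAGGTGGTGCTAC	TGG	forward
gAdprhl1-e7-2S	GGTGTCTTTATGGATTGCTCTA	TGG	forward
gAdprhl1-e7-2L	GGTGTCTGTATGGATTGCTCTA	TGG	forward
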