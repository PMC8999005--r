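disease_id	term_id	depth
dis001	dis001	0
dis001	C0027765	1
dis001	C0012634	2
dis001	ROOT	3
dis002	dis002	0
dis002	C0027765	1
dis002	C0012634	2
dis002	ROOT	3
dis003	dis003	0
dis003	C0018799	1
dis003	C0012634	2
dis003	ROOT	3
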