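disease_id	term_id	parent_term_id
dis001	dis001	C0027765
dis001	C0027765	C0012634
dis001	C0012634	ROOT
dis002	dis002	C0027765
dis002	C0027765	C0012634
dis002	C0012634	ROOT
dis003	dis003	C0018799
dis003	C0018799	C0012634
dis003	C0012634	ROOT
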