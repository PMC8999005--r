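id	dis001	dis002	dis003
drug001	1	0	0
drug002	0	1	1
drug003	0	0	0
drug004	1	1	0
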