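pathway	clone1	clone2	clone3
pathway1	1	1	0
pathway2	0	0	1
pathway3	0	0	1
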