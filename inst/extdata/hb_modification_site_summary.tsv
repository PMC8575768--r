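rrna_id	nm	psi
LSU	107	23
SSU	74	16
5.8S	2	2
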