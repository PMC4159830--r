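metric	n
n_pav	104
n_detected_by_tags	37
n_expressed_collectively	22789
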