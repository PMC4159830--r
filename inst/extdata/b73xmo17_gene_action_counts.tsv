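class	n
additivity	767
HPD	1984
LPD	2559
ODO	1085
UDO	1963
other	263
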