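class	n
P_only_present_hybrid	942
P_only_absent_hybrid	1682
M_only_present_hybrid	1117
M_only_absent_hybrid	854
absent_parents_present_hybrid	1065
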