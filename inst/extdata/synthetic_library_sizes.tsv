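stage	total_reads
egg	1368215
hpf24	2320145
hpf36	2053661
hpf48	810777
hpf72	1026553
dpf4	2421049
dpf10	2436524
dpf15	1500000
mo1pre	2121875
mo1post	845390
mo3	1041470
male	1828114
female	2288092
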