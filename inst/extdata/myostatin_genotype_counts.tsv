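group	panel	n_pp	n_pm	n_mm
Quarter Horse	A	9	5	6
Andalusian	A	0	3	17
Lipizzaner	A	0	0	23
Norwegian Fjord	A	0	0	20
Icelandic Pony	A	0	0	19
Przewalski's Horse	A	0	0	20
Show Jumpers	B	0	1	29
Italian Trotters	B	0	0	90
Unselected Thoroughbreds	B	18	29	28
Elite Thoroughbreds	B	33	69	15
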