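tier	count	mean_length	total_bases
M	10413	715	7442262
W	3322	468	1554812
A	2458	457	1122134
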