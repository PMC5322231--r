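library	paired_reads	mean_length_raw	retained_reads	mean_length_trimmed	broken_reads
DF	5801548	151	4905542	105	228878
DR	20157262	123	17645418	110	750518
RF	23573618	131	20549048	115	1066277
RR	6324432	151	5360350	108	250814
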