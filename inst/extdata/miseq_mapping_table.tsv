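library	mapped_reads	mean_mapped_length	contigs	contig_mean_length	contig_bases
DF	3151998	102.07	11095	310	3437391
DR	14041207	110.40	10118	315	3187663
RF	14975129	113.87	15829	467	7385140
RR	3511609	105.10	9387	291	2732913
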