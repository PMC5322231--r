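quantity	value
n_contigs	20981
n50	546
mapped_reads	35823839
mean_read_length	110
total_contig_bases	10119208
tier1_mapped_contigs	14785
tier2_input_contigs	6196
tier2_mapped_contigs	3738
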