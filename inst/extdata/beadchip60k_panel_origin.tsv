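row	count
chromosome_selected	59581
unplaced_contig	790
chr_random	421
mito	8
dbsnp_validated	17545
dbsnp_not_validated	24350
rrl_not_in_dbsnp	18758
rrl_and_dbsnp	7793
unmapped	1211
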