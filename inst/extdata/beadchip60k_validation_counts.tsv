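group	failed	excluded	monomorphic	polymorphic
All SNPs	3164	1116	2227	54293
dbSNP confirmed	893	64	27	16629
dbSNP random	886	764	1581	14087
Illumina sequencing	1431	285	618	24356
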