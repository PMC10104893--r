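chrT	toy	gene	5001	8000	.	+	.	gene_id "G1"; gene_biotype "protein_coding";
chrT	toy	gene	10001	11000	.	+	.	gene_id "G2"; gene_biotype "protein_coding";
chrT	toy	gene	20001	22000	.	-	.	gene_id "G3"; gene_biotype "lncRNA";
chrT	toy	gene	30001	32000	.	+	.	gene_id "G4"; gene_biotype "pseudogene";
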