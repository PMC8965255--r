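chr1	ensembl	exon	240562423	240564000	.	-	.	transcript_id "ENSRNOT00000024093"; gene_id "ENSRNOG00000017938";
chr1	ensembl	exon	240565000	240565400	.	-	.	transcript_id "ENSRNOT00000024093"; gene_id "ENSRNOG00000017938";
chr1	aptardi	exon	240561896	240564000	.	-	.	transcript_id "ENSRNOT00000024093.1"; gene_id "ENSRNOG00000017938";
chr1	aptardi	exon	240565000	240565400	.	-	.	transcript_id "ENSRNOT00000024093.1"; gene_id "ENSRNOG00000017938";
chr12	stringtie	exon	39010000	39012000	.	-	.	transcript_id "MSTRG.6250.1"; gene_id "MSTRG.6250";
chr12	stringtie	exon	39014000	39015000	.	-	.	transcript_id "MSTRG.6250.1"; gene_id "MSTRG.6250";
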