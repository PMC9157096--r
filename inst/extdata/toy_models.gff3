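##gff-version 3
chr1	toy	gene	100	500	.	+	.	ID=geneA
chr1	toy	mRNA	100	500	.	+	.	ID=geneA_t1;Parent=geneA
chr1	toy	exon	100	200	.	+	.	ID=geneA_t1.e1;Parent=geneA_t1
chr1	toy	exon	400	500	.	+	.	ID=geneA_t1.e2;Parent=geneA_t1
chr1	toy	mRNA	100	500	.	+	.	ID=geneA_t2;Parent=geneA
chr1	toy	exon	100	200	.	+	.	ID=geneA_t2.e1;Parent=geneA_t2
chr1	toy	exon	300	350	.	+	.	ID=geneA_t2.e2;Parent=geneA_t2
chr1	toy	exon	400	500	.	+	.	ID=geneA_t2.e3;Parent=geneA_t2
chr1	toy	gene	220	260	.	-	.	ID=geneB
chr1	toy	mRNA	220	260	.	-	.	ID=geneB_t1;Parent=geneB
chr1	toy	exon	220	260	.	-	.	ID=geneB_t1.e1;Parent=geneB_t1
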