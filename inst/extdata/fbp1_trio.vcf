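##fileformat=VCFv4.2
##source=fbppheno-fixture
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Coding consequence">
##INFO=<ID=HGVSC,Number=1,Type=String,Description="HGVS coding-sequence notation">
##INFO=<ID=UNIDIR,Number=0,Type=Flag,Description="Variant supported only by unidirectional reads">
##INFO=<ID=SIMREP,Number=0,Type=Flag,Description="Indel within a simple repeat region">
##INFO=<ID=AF_1KG,Number=1,Type=Float,Description="1000 Genomes allele frequency">
##INFO=<ID=AF_ESP,Number=1,Type=Float,Description="ESP6500 allele frequency">
##INFO=<ID=AF_HGVD,Number=1,Type=Float,Description="HGVD allele frequency">
##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description="ExAC allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	PROBAND	FATHER	MOTHER
9	97365012	fbp1_c581	A	G	60	PASS	GENE=FBP1;CSQ=missense;HGVSC=c.581T>C;AF_1KG=0.0002;AF_ESP=0;AF_HGVD=0.0003;AF_EXAC=0.0001	GT:DP:AD	0/1:34:18,16	0/0:31:31,0	0/1:29:15,14
9	97368740	fbp1_c491	C	T	60	PASS	GENE=FBP1;CSQ=missense;HGVSC=c.491G>A;AF_1KG=0;AF_ESP=0;AF_HGVD=0;AF_EXAC=0	GT:DP:AD	0/1:30:15,15	0/1:28:15,13	0/0:33:33,0
9	97401220	syn_fodder	G	A	55	PASS	GENE=ZNF169;CSQ=synonymous;AF_1KG=0;AF_ESP=0;AF_HGVD=0;AF_EXAC=0	GT:DP:AD	0/1:40:21,19	0/1:38:19,19	0/1:36:18,18
11	61520033	lowdp_fodder	T	C	30	PASS	GENE=FADS1;CSQ=missense;AF_1KG=0;AF_ESP=0;AF_HGVD=0;AF_EXAC=0	GT:DP:AD	0/1:7:3,4	0/0:25:25,0	0/1:26:13,13
2	21229160	known_fodder	C	T	50	PASS	GENE=APOB;CSQ=missense;AF_1KG=0.012;AF_ESP=0.009;AF_HGVD=0.015;AF_EXAC=0.011	GT:DP:AD	0/1:45:23,22	0/1:44:22,22	0/0:41:41,0
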