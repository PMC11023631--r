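##fileformat=VCFv4.2
##source=synthetic fixture: 10 hand-written records for filter demonstrations (not real sequencing data)
##contig=<ID=intIA_synthetic,length=960>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##INFO=<ID=AO,Number=A,Type=Integer,Description="Alternate allele observation count">
##INFO=<ID=RO,Number=1,Type=Integer,Description="Reference allele observation count">
##INFO=<ID=SAF,Number=A,Type=Integer,Description="Alternate allele observations on the forward strand">
##INFO=<ID=SAR,Number=A,Type=Integer,Description="Alternate allele observations on the reverse strand">
##INFO=<ID=SRF,Number=1,Type=Integer,Description="Reference allele observations on the forward strand">
##INFO=<ID=SRR,Number=1,Type=Integer,Description="Reference allele observations on the reverse strand">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
intIA_synthetic	21	.	G	A	.	.	DP=10000;AO=2;RO=9998;SAF=1;SAR=1;SRF=4999;SRR=4999
intIA_synthetic	57	.	CA	C	.	.	DP=10600;AO=53;RO=10547;SAF=27;SAR=26;SRF=5274;SRR=5273
intIA_synthetic	103	.	T	C	.	.	DP=10000;AO=2;RO=9998;SAF=2;SAR=0;SRF=5001;SRR=4997
intIA_synthetic	216	.	A	AT	.	.	DP=10600;AO=53;RO=10547;SAF=26;SAR=27;SRF=5273;SRR=5274
intIA_synthetic	305	.	C	T	.	.	DP=6000;AO=30;RO=5970;SAF=30;SAR=0;SRF=2985;SRR=2985
intIA_synthetic	442	.	G	T	.	.	DP=10600;AO=53;RO=10547;SAF=25;SAR=28;SRF=5270;SRR=5277
intIA_synthetic	518	.	T	A	.	.	DP=10000;AO=2;RO=9998;SAF=0;SAR=2;SRF=4998;SRR=5002
intIA_synthetic	640	.	AC	GT	.	.	DP=10600;AO=53;RO=10547;SAF=28;SAR=25;SRF=5275;SRR=5272
intIA_synthetic	775	.	G	GA	.	.	DP=10600;AO=53;RO=10547;SAF=26;SAR=27;SRF=5272;SRR=5275
intIA_synthetic	902	.	C	G	.	.	DP=10000;AO=2;RO=9998;SAF=1;SAR=1;SRF=5000;SRR=4998
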