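lncRNA_seqname	lncRNA_symbol	lncRNA_fold_change	lncRNA_regulation	genome_relationship	gene_seqname	gene_symbol	gene_fold_change	gene_regulation
ENSMUST00000145435	2010012P19Rik	6.0917526	down	natural_antisense	NM_001034097	Tnfsf12-Tnfsf13	2.0415635	down
AK017289	AK017289	5.792853	up	natural_antisense	NM_001267808	H2-L	2.8392743	up
AK017289	AK017289	5.792853	up	natural_antisense	NM_010380	H2-D1	2.6094529	up
AK155933	AK155933	4.4353006	down	intronic_antisense	NM_146191	Lrrk1	2.53359	down
AK087052	AK087052	3.4286643	up	intronic_antisense	NM_001035242	Trpm3	2.0411979	down
AK087052	AK087052	3.4286643	up	intronic_antisense	NM_001035243	Trpm3	2.0100955	down
AK149710	AK149710	3.163844	down	natural_antisense	NM_008850	Pitpna	2.4984672	down
AK158573	AK158573	2.5693914	down	natural_antisense	NM_028803	Gbe1	2.5839838	down
ENSMUST00000148180	Gm15396	2.5550359	down	natural_antisense	NM_008437	Napsa	4.8828493	down
AK007047	AK007047	2.510748	down	natural_antisense	NM_001200023	Zfp963	3.3589015	up
ENSMUST00000124513	Gm15247	2.064782	down	natural_antisense	NM_183151	Mid1	3.2269554	down
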