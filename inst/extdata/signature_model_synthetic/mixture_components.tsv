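feature	component	family	mean	sd	lambda	weight	scale
segsize	segsize_1	gaussian	4.4	0.09	NA	0.13950496495726	log10
segsize	segsize_2	gaussian	4.8	0.09	NA	0.145936662800276	log10
segsize	segsize_3	gaussian	5.2	0.09	NA	0.0875205327851829	log10
segsize	segsize_4	gaussian	5.6	0.09	NA	0.0962790316618012	log10
segsize	segsize_5	gaussian	6	0.09	NA	0.118991647899606	log10
segsize	segsize_6	gaussian	6.4	0.09	NA	0.125398047215229	log10
segsize	segsize_7	gaussian	6.8	0.09	NA	0.0967431926699987	log10
segsize	segsize_8	gaussian	7.2	0.09	NA	0.103917618912796	log10
segsize	segsize_9	gaussian	7.6	0.09	NA	0.085708301097849	log10
changepoint	changepoint_1	gaussian	1	0.15	NA	0.0762754334814235	identity
changepoint	changepoint_2	gaussian	2	0.15	NA	0.153344130386166	identity
changepoint	changepoint_3	gaussian	3	0.15	NA	0.125979390076922	identity
changepoint	changepoint_4	gaussian	4	0.15	NA	0.124073235204817	identity
changepoint	changepoint_5	gaussian	5	0.15	NA	0.311670545336746	identity
changepoint	changepoint_6	gaussian	6	0.15	NA	0.208657265513925	identity
bp10MB	bp10MB_1	poisson	NA	NA	2	0.350655435199012	identity
bp10MB	bp10MB_2	poisson	NA	NA	12	0.195816580098914	identity
bp10MB	bp10MB_3	poisson	NA	NA	45	0.453527984702074	identity
bpchrarm	bpchrarm_1	poisson	NA	NA	2	0.310859121875936	identity
bpchrarm	bpchrarm_2	poisson	NA	NA	14	0.266534819703609	identity
bpchrarm	bpchrarm_3	poisson	NA	NA	50	0.422606058420455	identity
osCN	osCN_1	poisson	NA	NA	3	0.341299335965279	identity
osCN	osCN_2	poisson	NA	NA	15	0.443908259256346	identity
osCN	osCN_3	poisson	NA	NA	45	0.214792404778375	identity
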