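chrom	pos_bp	cM
chr1	1	0
chr1	2.48e+08	302.3337
chr2	1	0
chr2	2.42e+08	295.0192
chr3	1	0
chr3	1.98e+08	241.3793
chr4	1	0
chr4	1.9e+08	231.6266
chr5	1	0
chr5	1.81e+08	220.6548
chr6	1	0
chr6	1.71e+08	208.4639
chr7	1	0
chr7	1.59e+08	193.8349
chr8	1	0
chr8	1.45e+08	176.7677
chr9	1	0
chr9	1.38e+08	168.2341
chr10	1	0
chr10	1.34e+08	163.3577
chr11	1	0
chr11	1.35e+08	164.5768
chr12	1	0
chr12	1.33e+08	162.1386
chr13	1	0
chr13	1.14e+08	138.976
chr14	1	0
chr14	1.07e+08	130.4424
chr15	1	0
chr15	1.02e+08	124.3469
chr16	1	0
chr16	9e+07	109.7179
chr17	1	0
chr17	8.3e+07	101.1843
chr18	1	0
chr18	8e+07	97.527
chr19	1	0
chr19	5.9e+07	71.9262
chr20	1	0
chr20	6.4e+07	78.0216
chr21	1	0
chr21	4.7e+07	57.2971
chr22	1	0
chr22	5.1e+07	62.1735
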