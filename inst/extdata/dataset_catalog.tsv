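dataset	type	species	cell_type	size
DeepHF_WT	high_throughput	Human	HEK293T	55604
DeepHF_Esp	high_throughput	Human	HEK293T	58167
DeepHF_HF	high_throughput	Human	HEK293T	56888
CRISPRon	high_throughput	Human	HEK293T	23902
doench2014-Hs	functional_U6	Human	MOLM13/NB4/TF1	881
doench2014-Mm	functional_U6	Mouse	EL4	951
xu2015TrainHl60	functional_U6	Human	HL60	2076
xu2015TrainKbm7	functional_U6	Human	KBM7	2076
doench2016_hg19	functional_U6	Human	A375	2333
doench2016plx_hg19	functional_U6	Human	A375	2333
chari2015Train293T	functional_U6	Human	HEK293T	1234
hart2016-Rpe1Avg	functional_U6	Human	Rpe	4214
hart2016-HelaLib2Avg	functional_U6	Human	Hela	3845
hart2016-Hct1162lib1Avg	functional_U6	Human	Hct116	4239
hart2016-HelaLib1Avg	functional_U6	Human	Hela	4256
morenoMateos2015	functional_T7	Zebrafish	1-cell_embryos	1020
leenay	endogenous	Human	T	1656
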