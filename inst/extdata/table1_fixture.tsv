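# Transcription of the published table of citrullinated peptides and
# low-temperature-induced citrullination events in Arabidopsis thaliana.
# section: control = baseline citrullination signature; differential =
# changed on cold treatment; de_novo = absent in control, appearing after
# cold treatment. fc_1h / fc_24h: fold change vs control, or ns (no
# significant change), nd (not detected), "at 1 h"/"at 24 h" (de novo
# detection at that timepoint only).
# Lowercase letters inside peptide bodies reproduce the printed table and
# are unexplained there beyond m (oxidized methionine); the loader
# case-folds them and records their positions.
# Note: the source prose refers to the exostosin-family protein as
# At2g29040 while its table prints AT1G29040; the table spelling is kept.
section	accession	description	mascot_score	mass	peptide	pep_score	expect	fc_1h	fc_24h
control	AT1G50030	Target of rapamycin (TOR)	59	281237	R.ERAVEALR.A	59	0.0003	ns	ns
control	AT1G26110	Decapping 5 (DCP5)	47	64331	R.GYGGyGGRGGGGGGyGyGGRGQGR.G	47	0.007	ns	ns
control	AT5G17860	Calcium exchanger 7 (CAX7)	40	62679	K.RMSDQILR.S	39	0.033	ns	ns
control	AT4G12850	Far-red impaired responsive (FAR1)	37	21522	K.VRDIVENVKK.L	36	0.035	ns	ns
control	AT4G31890	Armadillo (ARM) repeat protein	35	56650	R.VtLAMLGAIPPLVSmIDDsR.I	35	0.0097	ns	ns
control	AT4G27810	Hypothetical DUF688 protein	34	22156	R.RSLSVIR.R	34	0.031	ns	ns
control	AT3G02890	RING/FYVE/PHD zinc finger	33	110280	R.RVGNRPMGRR.G	33	0.022	ns	ns
control	AT4G00830	RNA-binding family protein	33	55273	R.NNGSSGGSGRDNSHEHDGNRGGR.R	33	0.027	ns	ns
control	AT4G09980	Methyltransferase MT-A70	32	86022	R.ERTHGSSSDSSK.R	32	0.024	ns	ns
control	AT4G10000	Thioredoxin family protein	30	37375	R.ISGNGNWVRER.R	30	0.018	ns	ns
differential	AT2G21450	Chromatin remodeling 34 (CHR34)	68	94037	K.ETYmLSSLARVKTR.R	41	0.0018	1.90	1.84
differential	AT5G27920	F-box family protein	41	72636	R.ARGLETLAR.M	47	0.0029	1.86	1.53
differential	AT4G19180	GDA1/CD39 nucleoside phosphatase	37	82544	R.FQRWSPMSTGVK.T	37	0.0077	1.9	1.8
differential	AT1G29040	Hypothetical exostosin family prot.	33	20111	K.FLSSRSK.Q	33	0.013	ns	0.67
de_novo	AT1G24290	AAA-type ATPase family protein	37	57702	K.SMRGGDANAAIYWLAR.M	35	0.013	at 1 h	at 24 h
de_novo	ATCG00520	YCF4 (unfolded protein binding)	35	21564	K.DIQsIRIEVK.E	35	0.014	at 1 h	nd
de_novo	AT1G16950	Hypothetical protein	34	10044	.MARPRIsIsmICLLILIVGFVLQssQAR.K	34	0.0071	nd	at 24 h
de_novo	AT2G23790	Unknown DUF607 protein	32	38438	K.LLRAAQIEIVK.S	32	0.02	at 1 h	nd
de_novo	AT2G47650	UDP-xylose synth. 4	32	50085	R.VVVtGGAGFVGSHLVDRLmAR.G	32	0.0087	nd	at 24 h
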