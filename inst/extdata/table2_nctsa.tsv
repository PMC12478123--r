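sample	peptide	region_reconstructed	max_tpm_control	nr_class	min_tpm_diff	min_tpm_novel	correct_rf	correct_orf	hla_match
07H103	KILILLQSL	YES	-	novel	-	6.9	NO	-	-
07H103	KISLYLPAL	NO	-	-	-	-	-	-	-
07H103	SLTALVFHV	YES	-	novel	-	876.4	NO	-	-
10H080	HETLRLLL	NO	-	-	-	-	-	-	-
10H080	TSIPKPNLK	YES	-	novel	-	1.7	YES	NO	-
10H080	RIFGFRLWK	YES	-	novel	-	7.4	YES	YES	YES
10H080	TSFAETWMK	NO	0.8	-	-	-	-	-	-
10H118	LPFEQKSL	NO	-	-	-	-	-	-	-
10H118	SLREKGFSI	NO	-	-	-	-	-	-	-
10H118	VPAALRSL	YES	-	novel	-	1.5	YES	YES	YES
12H018	LLAATILLSV	NO	-	-	-	-	-	-	-
12H018	SLTALVFHV	YES	-	novel	-	1925.3	NO	-	-
lc2	IIAPPPPPK	YES	19.6	-	-	-	-	-	-
lc2	LVFNIILHR	YES	-	novel	-	0.4	-	-	-
lc2	MISPVLALK	YES	-	novel	-	43.5	YES	NO	-
lc2	SLSYLILKK	YES	1	differential	0.3	-	-	-	-
lc2	SSASQLPSK	YES	0.9	differential	133.3	-	NO	-	-
lc2	SVIQTGHLAK	YES	0.5	differential	48.4	-	YES	YES	YES
lc2	TTLKYLWKK	YES	1.5	-	-	-	-	-	-
lc4	KPSVFPLSL	YES	1.6	-	-	-	-	-	-
lc6	QR/KF/LQGRVTM	YES	2.3	-	-	-	-	-	-
lc6	SRFSGVPDRF	YES	0.8	differential	1475.8	-	YES	YES	YES
lc6	TYTQN/DFNKF	YES	1.7	-	-	-	-	-	-
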