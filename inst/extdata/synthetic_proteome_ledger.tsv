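seq_id	kind	decoy_kind	tripeptide	motif_start	left_spacer	right_spacer	expected_detection
SIPHO_100001	motif		WGD	52	16	2	TRUE
SIPHO_100001	signal			NA	NA	NA	FALSE
CERAT_100002	motif		RGD	44	13	3	TRUE
CERAT_100002	signal			NA	NA	NA	TRUE
CERAT_100003	signal			NA	NA	NA	TRUE
CIMIC_100004	motif		WGD	90	4	11	TRUE
CIMIC_100004	signal			NA	NA	NA	TRUE
TABAN_100005	motif		WGD	41	12	16	TRUE
TABAN_100005	signal			NA	NA	NA	TRUE
SIMUL_100006	signal			NA	NA	NA	TRUE
PSYCH_100007	decoy	spacer17	RTS	113	17	14	FALSE
PSYCH_100007	signal			NA	NA	NA	TRUE
HIRUD_100008	motif		VGD	44	8	15	TRUE
HIRUD_100008	signal			NA	NA	NA	FALSE
SIPHO_100009	motif		VGD	107	9	10	TRUE
SIPHO_100009	signal			NA	NA	NA	FALSE
TABAN_100010	motif		VGD	137	15	6	TRUE
TABAN_100010	signal			NA	NA	NA	FALSE
IXODO_100011	motif		WGD	50	7	15	TRUE
IXODO_100011	motif		RED	88	7	9	TRUE
IXODO_100011	signal			NA	NA	NA	TRUE
HIRUD_100012	decoy	in_signal	KGD	4	0	0	TRUE
HIRUD_100012	signal			NA	NA	NA	TRUE
SIPHO_100001	accidental		KGD	67	9	10	TRUE
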