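family	allfam_id	n	mean_identity_pct	mean_similarity_pct	min_identity_pct	max_identity_pct	min_similarity_pct	max_similarity_pct	reported_mean_arisc
Papain-like cysteine proteases	AF030	15	37	50	21	85	30	88	0.42
NPC2 family	AF111	17	41	58	22	90	34	95	0.48
Serum albumins	AF056	14	71	80	43	99	56	99	0.74
Pectate lyases	AF073	14	64	70	44	98	51	98	0.64
Lipocalins	AF015	29	21	33	4	95	7	98	0.26
Beta-expansins and expansin-related	AF093	27	56	67	24	99	38	99	0.61
Group V/VI grass pollen allergens	AF102	13	57	66	13	82	23	85	0.60
Profilins	AF051	64	76	84	32	99	43	99	0.80
nsLTPs	AF050	51	51	61	18	99	25	99	0.56
PR-10 (Bet v 1 family)	AF069	46	52	65	15	98	28	98	0.58
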