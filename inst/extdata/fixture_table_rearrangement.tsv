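# Cohort fixture: per-group embryo classification counts.
# 'Other' row type split is reconstructed (totals constrained), see docs.
#group	biopsied	informative	euploid	typeI	typeII	typeIII	typeIV
RecT	670	629	101	186	73	99	170
RobT	291	275	77	42	64	37	55
Inv	124	118	33	10	36	11	28
NoCR	139	132	41	1	65	0	25
Other	15	14	4	3	3	2	2
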