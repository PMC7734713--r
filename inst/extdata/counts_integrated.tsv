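# Expert-evaluation cells of the integrated cross-dataset method:
# query_id	dataset_id	correct	total
Q1	semmeddb	53	61
Q1	pharmgkb	23	23
Q1	uniprot	11	11
Q2	semmeddb	67	81
Q2	pharmgkb	42	42
Q3	semmeddb	48	55
Q3	pharmgkb	13	13
Q4	semmeddb	58	66
Q5	semmeddb	2	3
Q5	pharmgkb	25	25
Q6	semmeddb	34	40
Q6	pharmgkb	11	11
Q7	semmeddb	60	67
Q7	kegg	12	12
Q8	semmeddb	31	36
Q8	pharmgkb	11	11
Q9	semmeddb	23	26
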