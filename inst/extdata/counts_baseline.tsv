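# Expert-evaluation cells of the workshop-stage baseline fusion method:
# query_id	dataset_id	correct	total
Q1	semmeddb	48	56
Q1	pharmgkb	23	23
Q1	uniprot	11	11
Q2	semmeddb	56	73
Q2	pharmgkb	42	42
Q3	semmeddb	44	52
Q3	pharmgkb	13	13
Q4	semmeddb	54	63
Q5	pharmgkb	25	25
Q6	semmeddb	29	36
Q6	pharmgkb	11	11
Q7	semmeddb	54	61
Q7	kegg	12	12
Q8	semmeddb	25	32
Q8	pharmgkb	11	11
Q9	semmeddb	19	23
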