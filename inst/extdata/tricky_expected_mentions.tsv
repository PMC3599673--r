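doc_id	sent_index	char_start	char_end	surface	etype	norm_id
d1	0	0	4	IL-6	gene	IL6
d1	2	0	4	BSF2	gene	IL6
d1	2	11	20	TNF-alpha	gene	TNF
d2	0	0	2	AB	gene	AB
d2	0	13	18	MAPK1	gene	MAPK1
d2	2	0	4	ERK2	gene	MAPK1
d2	2	9	13	erk2	gene	MAPK1
d3	0	0	11	BCG vaccine	vaccine_specific	VO:0000101
d3	1	4	11	vaccine	vaccine_general	vaccine
d3	2	0	5	IFN-γ	gene	IFNG
d3	2	24	35	vaccination	vaccine_general	vaccine
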