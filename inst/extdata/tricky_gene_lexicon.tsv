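symbol	name	synonyms
IL6	interleukin 6	IL-6|BSF2
TNF	tumor necrosis factor	TNF-alpha|TNFA
AB	antigen binder	
MAPK1	mitogen-activated protein kinase 1	p40|ERK2
MAPK3	mitogen-activated protein kinase 3	p40|ERK1
IFNG	interferon gamma	IFN-γ
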