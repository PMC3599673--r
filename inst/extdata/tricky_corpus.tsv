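doc_id	title	abstract
d1	IL-6 induces fever	The protein p40 was elevated. BSF2 binds TNF-alpha in serum.
d2	AB activates MAPK1	The ab fraction is unrelated. ERK2 and erk2 both appear here.
d3	BCG vaccine reduced fever	The vaccine was safe. IFN-γ levels rose after vaccination.
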