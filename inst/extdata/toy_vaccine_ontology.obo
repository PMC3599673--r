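format-version: 1.2
ontology: toy-vaccine-ontology

[Term]
id: VO:0000001
name: vaccine

[Term]
id: VO:0000002
name: live attenuated vaccine
is_a: VO:0000001 ! vaccine

[Term]
id: VO:0000101
name: BCG vaccine
synonym: "Bacillus Calmette-Guerin vaccine" EXACT []
is_a: VO:0000002 ! live attenuated vaccine

[Term]
id: VO:0000102
name: flu vaccine
is_a: VO:0000001 ! vaccine

[Term]
id: VO:0000103
name: smallpox vaccine
is_a: VO:0000001 ! vaccine
is_obsolete: true
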