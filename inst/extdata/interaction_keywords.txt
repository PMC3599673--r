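# Interaction trigger keywords, one per line; matched case-insensitively
# at token boundaries after light stemming, so each entry covers its
# inflected forms ("bind" also matches "binds", "binding", "bound" is
# listed separately).
bind
bound
activate
induce
inhibit
suppress
regulate
interact
stimulate
phosphorylate
dephosphorylate
associate
block
mediate
modulate
promote
enhance
attenuate
upregulate
downregulate
up-regulate
down-regulate
trigger
repress
transactivate
degrade
cleave
recruit
target
ligate
antagonize
agonize
sequester
stabilize
destabilize
ubiquitinate
acetylate
methylate
cross-link
complex
heterodimerize
dimerize
cooperate
synergize
potentiate
abolish
abrogate
neutralize
elicit
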