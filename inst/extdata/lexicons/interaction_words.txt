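# interaction trigger words (verbs and nominalizations), lowercased
interact
interacts
interacted
interaction
interactions
bind
binds
bound
binding
associate
associates
associated
association
complex
complexes
phosphorylate
phosphorylates
phosphorylated
phosphorylation
activate
activates
activated
activation
inhibit
inhibits
inhibited
inhibition
regulate
regulates
regulated
regulation
stimulate
stimulates
stimulated
suppress
suppresses
suppressed
induce
induces
induced
mediate
mediates
mediated
modulate
modulates
modulated
cleave
cleaves
cleaved
recruit
recruits
recruited
target
targets
targeted
dimerize
dimerizes
heterodimer
homodimer
coprecipitate
coimmunoprecipitate
crosslink
ubiquitinate
ubiquitinated
acetylate
acetylated
represses
repressed
enhances
enhanced
blocks
blocked
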