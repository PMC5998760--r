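# Example prescription-drug lexicon, one name per line.
# Multi-word names are allowed and matched longest-first.
humira
dronedarone
lamictal
pradaxa
paxil
zoledronic acid
trazodone
enbrel
cymbalta
quetiapine
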