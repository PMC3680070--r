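# negation words, lowercased
not
no
neither
nor
none
never
without
lack
lacks
lacking
lacked
absence
absent
unable
cannot
fail
fails
failed
failure
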