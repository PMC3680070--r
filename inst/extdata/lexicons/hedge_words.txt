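# hedge / speculation words, lowercased
may
might
could
can
possibly
possible
probably
probable
likely
unlikely
suggest
suggests
suggested
suggesting
appear
appears
appeared
seem
seems
seemed
potentially
potential
putative
putatively
presumably
perhaps
hypothesize
hypothesized
indicate
indicates
indicated
propose
proposed
speculate
whether
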