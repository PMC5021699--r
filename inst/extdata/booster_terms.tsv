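# Booster terms: term<TAB>shift, shift in {-1, +1, +2}.
very	1
really	1
extremely	2
incredibly	2
totally	1
quite	1
somewhat	-1
slightly	-1
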