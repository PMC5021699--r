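# Negator terms, one per line.
not
never
no
nothing
nobody
cannot
isnt
dont
wont
didnt
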