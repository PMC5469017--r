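# Abbreviation patterns, one regular expression per line.
# Each pattern is matched case-insensitively with token-boundary guards
# added by the recognizer; the normalized match must resolve through the
# term dictionary to map to a concept.
lvef
lvedd
lvesd
lvidd
lvids
lvh
lvpwd?
ivsd?
ava
mva
pasp?
rap
ef
lvd\s*ed
lvd\s*es
e/e'?
e\s+to\s+e\s+prime
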