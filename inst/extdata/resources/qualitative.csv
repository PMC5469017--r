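# Qualitative value lexicon: surface,grade_rank
# Ranks impose a total severity order so ranges like "low to moderate"
# have low <= high. Distinct surfaces may share a rank.
normal,0
preserved,0
hyperdynamic,1
trace,1
trivial,1
borderline,1
low,2
reduced,2
depressed,2
mild,2
mildly reduced,2
mildly depressed,2
moderate,3
moderately reduced,3
moderately depressed,3
moderately severe,4
severe,5
severely reduced,5
severely depressed,5
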