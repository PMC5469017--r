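# Mutual-exclusion constraint pairs between semantic groups: group_a,group_b
# A candidate concept tagged with a group that is mutually exclusive with a
# group named by a word inside the query phrase is discarded during mapping.
atrium,ventricle
atrium,mitral
atrium,tricuspid
volume,dimension
volume,velocity
volume,pressure
mitral,tricuspid
aortic,mitral
aortic,tricuspid
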