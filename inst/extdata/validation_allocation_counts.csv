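region,agreement,disagreement
olfactory areas,68,9
isocortex,383,22
corpus callosum,33,11
hippocampal region,129,5
striatum,96,8
thalamus and midbrain,261,8
other,25,2
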