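workflow,level_label,agreement,not_at_level,disagreement
blockface,10,18,27,7
blockface,9,29,16,7
blockface,8,39,8,5
blockface,7,45,4,3
blockface,6,50,0,2
blockface,5,50,0,2
blockface,3/4,50,0,2
blockface,1/2,51,0,1
histology,10,22,20,10
histology,9,30,14,8
histology,8,40,4,8
histology,7,45,1,6
histology,6,48,0,4
histology,5,49,0,3
histology,3/4,50,0,2
histology,1/2,51,0,1
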