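path1,path2,sorensen,jaccard
AH,DD,0.290,0.170
AH,MN,0.329,0.197
AH,NO,0.309,0.183
AH,ST,0.322,0.192
DD,MN,0.292,0.171
DD,NO,0.240,0.136
DD,ST,0.238,0.135
MN,NO,0.378,0.233
MN,ST,0.366,0.224
NO,ST,0.460,0.298
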