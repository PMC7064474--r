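"hematoxylin","eosin","residual"
0.650028601887738,0.0721332449690492,0.331856878089249
0.704030978044566,0.991832118324427,0.0755933232768255
0.286012584830605,0.105194315579863,0.940296050156983
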