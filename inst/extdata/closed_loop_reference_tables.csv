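table,subject,a,b,c,d
type,1,4,1,1,6
type,2,8,1,8,10
type,3,1,2,6,5
type,4,4,2,6,2
type,5,4,11,4,7
onset,1,11,7,8,10
onset,2,21,14,4,11
onset,3,13,6,2,10
onset,4,12,7,5,9
onset,5,17,12,3,8
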