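subject_id,time,event,fibrate
1,1,1,1
2,2,1,0
3,3,0,1
4,4,0,0
5,5,1,1
6,6,0,0
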