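230,25,75
60,180,75
0,130,200
245,130,48
145,30,180
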