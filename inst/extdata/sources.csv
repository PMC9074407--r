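part,slot,well
GFP,1,A1
YFP,1,B1
DVK,1,C1
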