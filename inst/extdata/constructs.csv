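well,part1,part2
A1,GFP,DVK
B1,YFP,DVK
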