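NA Abl1_synthetic
P0 A C G T
01 24 14 3 3
02 32 4 4 4
03 24 14 3 3
04 32 4 4 4
05 32 4 4 4
06 24 14 3 3
07 14 24 3 3
08 32 4 4 4
09 32 4 4 4
10 3 24 14 3
11 32 4 4 4
12 24 3 14 3
//
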