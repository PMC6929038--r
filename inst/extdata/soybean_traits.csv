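variety,crude_protein_pct,crude_fat_pct
NanNong 1606,36.0,19.7
ShangDou 161,35.6,19.6
ShangDou 1201,43.1,20.2
ShangDou 1310,42.1,20.5
YuDou 18,44.5,18.8
YuDou 22,46.5,18.9
YuDou 25,46.3,17.1
Zheng 196,40.7,19.5
Zheng 3074,40.9,17.1
Zheng 9525,45.0,17.7
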