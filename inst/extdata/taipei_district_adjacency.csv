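district_a,district_b
Beitou,Shihlin
Shihlin,Jhongshan
Shihlin,Datong
Shihlin,Neihu
Neihu,Jhongshan
Neihu,Songshan
Neihu,Nangang
Songshan,Jhongshan
Songshan,Sinyi
Songshan,Daan
Songshan,Nangang
Nangang,Sinyi
Nangang,Wunshan
Sinyi,Daan
Sinyi,Wunshan
Daan,Wunshan
Daan,Jhongjheng
Daan,Jhongshan
Jhongshan,Datong
Jhongshan,Jhongjheng
Datong,Jhongjheng
Datong,Wanhua
Jhongjheng,Wanhua
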