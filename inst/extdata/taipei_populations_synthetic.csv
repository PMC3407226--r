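district,age_group,population
Songshan,preschool,16890
Songshan,school,21220
Songshan,all,38110
Sinyi,preschool,18780
Sinyi,school,23590
Sinyi,all,42370
Daan,preschool,25580
Daan,school,32140
Daan,all,57720
Jhongshan,preschool,17790
Jhongshan,school,22350
Jhongshan,all,40150
Jhongjheng,preschool,13120
Jhongjheng,school,16480
Jhongjheng,all,29600
Datong,preschool,10330
Datong,school,12980
Datong,all,23310
Wanhua,preschool,15500
Wanhua,school,19470
Wanhua,all,34970
Wunshan,preschool,21570
Wunshan,school,27090
Wunshan,all,48660
Nangang,preschool,9180
Nangang,school,11540
Nangang,all,20720
Neihu,preschool,20010
Neihu,school,25130
Neihu,all,45140
Shihlin,preschool,23450
Shihlin,school,29460
Shihlin,all,52910
Beitou,preschool,20500
Beitou,school,25750
Beitou,all,46250
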