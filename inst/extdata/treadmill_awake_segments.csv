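rodent,recording_id,seconds,rodent_total_s
AsiagoBleu,180626,3508,9500
AsiagoBleu,180627,1776,9500
AsiagoBleu,180628,1728,9500
AsiagoBleu,180629,2488,9500
bobmarley,102819,4236,18196
bobmarley,102919,4776,18196
bobmarley,103119,4228,18196
bobmarley,110319,3012,18196
bobmarley,110419,1944,18196
cheaptrick,110619,2480,17240
cheaptrick,110719,11608,17240
cheaptrick,111319,3152,17240
EZBrie,180707,4320,19064
EZBrie,180708,4320,19064
EZBrie,180709,3228,19064
EZBrie,180710,7196,19064
FetaMozz,180628,7124,17340
FetaMozz,180629,6860,17340
FetaMozz,180630,3356,17340
Manchego,180620,4456,16156
Manchego,180621,5396,16156
Manchego,180622,2188,16156
Manchego,180623,4116,16156
MuensterMonty,180720,3408,26956
MuensterMonty,180721,7648,26956
MuensterMonty,180723,5024,26956
MuensterMonty,180726,3380,26956
MuensterMonty,180727,7496,26956
NachoGouda,180705,2656,9140
NachoGouda,180706,2496,9140
NachoGouda,180707,2136,9140
NachoGouda,180708,1852,9140
neilyoung,111719,2840,26516
neilyoung,111819,3320,26516
neilyoung,111919,3272,26516
neilyoung,112119,3284,26516
neilyoung,112219,4148,26516
neilyoung,112619,4040,26516
neilyoung,112819,3200,26516
neilyoung,112919,2412,26516
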