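rotation,source,type,c1,c2,c3
rter,real,TYPE1,0,17,22
rter,real,TYPE2,50,183,158
rter,real,TYPE3,2,49,3
rter,psokm,TYPE1,0,19,27
rter,psokm,TYPE2,38,195,158
rter,psokm,TYPE3,8,37,2
rter,km,TYPE1,0,7,39
rter,km,TYPE2,44,206,142
rter,km,TYPE3,3,36,7
rtir,real,TYPE1,1,7,25
rtir,real,TYPE2,48,223,152
rtir,real,TYPE3,3,19,6
rtir,psokm,TYPE1,2,6,18
rtir,psokm,TYPE2,40,223,160
rtir,psokm,TYPE3,4,22,9
rtir,km,TYPE1,1,1,22
rtir,km,TYPE2,39,231,154
rtir,km,TYPE3,1,31,4
lter,real,TYPE1,1,16,20
lter,real,TYPE2,47,160,150
lter,real,TYPE3,4,73,13
lter,psokm,TYPE1,1,13,34
lter,psokm,TYPE2,35,190,132
lter,psokm,TYPE3,2,48,29
lter,km,TYPE1,2,7,33
lter,km,TYPE2,38,210,110
lter,km,TYPE3,1,66,17
ltir,real,TYPE1,3,14,34
ltir,real,TYPE2,49,218,147
ltir,real,TYPE3,0,17,2
ltir,psokm,TYPE1,2,10,39
ltir,psokm,TYPE2,42,218,154
ltir,psokm,TYPE3,2,11,6
ltir,km,TYPE1,3,16,45
ltir,km,TYPE2,42,202,170
ltir,km,TYPE3,0,3,3
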