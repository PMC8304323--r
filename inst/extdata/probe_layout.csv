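channel,source,detector,roi
1,1,1,LDLPFC
2,1,2,LDLPFC
3,2,1,LDLPFC
4,2,2,LDLPFC
5,2,3,MPFC
6,3,2,MPFC
7,3,3,MPFC
8,3,4,RDLPFC
9,4,3,RDLPFC
10,4,4,RDLPFC
11,4,5,RDLPFC
12,5,5,LPM
13,5,6,LPM
14,6,5,LPM
15,6,6,LPM
16,7,7,RPM
17,7,8,RPM
18,8,7,RPM
19,8,8,RPM
20,6,7,SMA
21,7,6,SMA
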