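taxon	PPP1R2P1	PPP1R2P2	PPP1R2P3	PPP1R2P4	PPP1R2P5	PPP1R2P6	PPP1R2P7	PPP1R2P8	PPP1R2P9	PPP1R2P10
Hosa	1	1	1	1	1	1	1	1	1	1
Patr	1	1	1	0	1	1	1	1	1	1
Gogo	1	1	1	0	1	1	1	1	1	1
Poab	1	1	1	0	1	1	1	1	1	1
Nole	1	1	1	0	1	1	1	?	1	1
Mamu	1	1	0	0	1	1	1	1	1	1
Chae	1	1	0	0	1	1	1	1	1	1
Caja	1	0	0	0	1	1	1	1	1	1
Mumu	0	0	0	0	0	0	0	0	1	0
Rano	0	0	0	0	0	0	0	0	1	0
Orcu	0	0	0	0	0	0	0	0	1	0
Cafa	0	0	0	0	0	0	1	0	1	0
Aime	0	0	0	0	0	0	1	0	1	0
Eqca	0	0	0	0	0	0	1	0	1	0
Bota	0	0	0	0	0	0	1	0	1	0
Susc	0	0	0	0	0	0	1	0	1	0
Loaf	0	0	0	0	0	0	1	0	1	0
Modo	0	0	0	0	0	0	0	0	1	0
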