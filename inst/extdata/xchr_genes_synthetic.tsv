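gene	chrom	start	end
RPGR	X	38100000	38200000
NYX	X	41300000	41350000
NDP	X	43800000	43830000
RP2	X	46690000	46740000
CACNA1F	X	49200000	49230000
CITED1	X	71500000	71510000
PGK1	X	78100000	78130000
CHM	X	85860000	86050000
TIMM8A	X	101340000	101350000
PRPS1	X	107600000	107630000
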