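name	chrom	position
DXS1060	X	3500000
DXS8051	X	7000000
DXS987	X	12000000
DXS1226	X	16500000
DXS1214	X	21000000
DXS1068	X	26000000
DXS993	X	31000000
DXS1055	X	36000000
DXS991	X	41000000
DXS986	X	47000000
DXS1217	X	53000000
DXS1204	X	59000000
DXS1194	X	65000000
DXS1111	X	71000000
DXS8055	X	77000000
DXS1001	X	83000000
DXS1231	X	89000000
DXS1059	X	95000000
DXS1220	X	101000000
DXS8059	X	106000000
DXS990	X	110000000
DXS1106	X	115000000
DXS1210	X	120000000
DXS8043	X	128000000
DXS8045	X	137000000
DXS1073	X	148000000
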