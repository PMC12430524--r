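variant	status	predicted
V600E	S	S
V600M	S	S
V600K	S	S
V600D	S	S
V600R	S	S
L505H	R	R
G466E	R	R
G469A	R	R
V600E+L514V	R	R
L597R	S	S
V600E+L505H	R	R
S467V	Unknown	S
G469V	Unknown	R
K601E	Unknown	R
L597S	Unknown	S
WT	Unknown	S
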