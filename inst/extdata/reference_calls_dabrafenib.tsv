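variant	status	predicted
V600E	S	S
V600M	S	S
V600K	S	S
V600D	S	S
V600R	S	S
G466E	R	R
WT	S	S
L597S	S	S
K601E	R	S
G469A	R	R
G469V	R	R
S467L	R	R
L505H	Unknown	S
L597R	Unknown	R
V600E+L505H	Unknown	R
V600E+L514V	Unknown	S
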