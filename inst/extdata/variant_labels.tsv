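variant	drug	status
V600E	dabrafenib	S
V600M	dabrafenib	S
V600K	dabrafenib	S
V600D	dabrafenib	S
V600R	dabrafenib	S
G466E	dabrafenib	R
WT	dabrafenib	S
L597S	dabrafenib	S
K601E	dabrafenib	R
G469A	dabrafenib	R
G469V	dabrafenib	R
S467L	dabrafenib	R
L505H	dabrafenib	Unknown
L597R	dabrafenib	Unknown
V600E+L505H	dabrafenib	Unknown
V600E+L514V	dabrafenib	Unknown
V600E	vemurafenib	S
V600M	vemurafenib	S
V600K	vemurafenib	S
V600D	vemurafenib	S
V600R	vemurafenib	S
L505H	vemurafenib	R
G466E	vemurafenib	R
G469A	vemurafenib	R
V600E+L514V	vemurafenib	R
L597R	vemurafenib	S
V600E+L505H	vemurafenib	R
S467V	vemurafenib	Unknown
G469V	vemurafenib	Unknown
K601E	vemurafenib	Unknown
L597S	vemurafenib	Unknown
WT	vemurafenib	Unknown
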