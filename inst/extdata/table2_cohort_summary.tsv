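characteristic	unit	mean	sd
age	years	29.72	4.36
fsh	IU/L	69.10	31.79
e2	pg/ml	21.33	16.73
bmi	kg/m2	21.37	6.64
menarche_age	years	14.62	3.04
onset_age	years	23.97	5.71
pa_fraction	fraction	0.227	
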