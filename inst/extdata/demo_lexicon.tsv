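word	happiness	sadness	anger	fear	disgust
radość	6.9	1.2	1.1	1.3	1.0
smutek	1.2	6.8	2.1	2.4	1.5
złość	1.1	2.3	6.6	2.0	2.2
strach	1.3	2.6	1.9	6.7	1.8
wstręt	1.0	2.0	2.4	2.1	6.4
boję	1.2	2.8	1.7	6.5	1.6
choroby	1.4	4.2	2.0	5.5	2.6
brzydkie	1.2	3.0	2.2	2.0	5.0
słabe	1.5	4.5	1.8	3.2	1.9
wstyd	1.3	4.8	2.2	3.6	3.9
zdrowe	5.8	1.4	1.2	1.5	1.1
piękne	6.2	1.3	1.1	1.2	1.0
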