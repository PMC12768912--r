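participant_id,t_min,glucose_mmol_l
P01,-2,5.1
P01,0,5.2
P01,30,7.9
P01,60,7.1
P01,90,5.8
P01,120,5.0
P02,-2,4.8
P02,0,4.9
P02,30,6.4
P02,60,6.9
P02,90,6.1
P02,120,5.2
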