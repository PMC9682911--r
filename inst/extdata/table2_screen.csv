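switch,model_e_pipi,model_z_pipi,exp_e_pipi,exp_z_pipi
1,456,368,446,355
2,459,377,441,356
3,457,377,399,331
4,463,373,445,357
5,471,381,450,370
6,460,368,451,360
7,467,369,534,
8,450,359,465,376
9,453,369,468,399
10,453,363,471,398
11,453,360,452,379
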