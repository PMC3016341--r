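time_d,EI_kcal_d,diet_name
0,13.5,high_fat
49,6,chow
56,10,chow
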