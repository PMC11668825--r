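region,year,g_per_kwh
DE,2022,361
NO,2022,30
SE,2022,45
FR,2022,85
US,2022,390
PL,2022,750
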