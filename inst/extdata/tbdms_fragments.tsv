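name	formula	n_backbone
Ala_M-57	C11H26NO2Si2	3
Gly_M-57	C10H24NO2Si2	2
Val_M-57	C13H30NO2Si2	5
Leu_M-57	C14H32NO2Si2	6
Ile_M-57	C14H32NO2Si2	6
Pro_M-57	C13H28NO2Si2	5
Met_M-57	C13H30NO2SSi2	5
Ser_M-57	C17H40NO3Si3	3
Thr_M-57	C18H42NO3Si3	4
Phe_M-57	C17H30NO2Si2	9
Asp_M-57	C18H40NO4Si3	4
Glu_M-57	C19H42NO4Si3	5
Lys_M-57	C20H47N2O2Si3	6
Tyr_M-57	C23H44NO3Si3	9
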