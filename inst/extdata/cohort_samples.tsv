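cohort	n_control	n_case
Obesity	105	95
T2D	185	183
ACVD	171	214
CD	53	49
CRC	57	90
LC	114	123
AS	114	93
RA	74	95
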