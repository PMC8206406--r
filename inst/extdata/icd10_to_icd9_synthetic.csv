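source_code,target_code
I10,401.9
E78.5,272.4
J18.9,486
J02.9,462
M54.5,724.2
K21.9,530.81
J45.909,493.90
R53.81,780.79
M79.1,729.5
M25.561,719.46
E11.9,250.00
F32.9,311
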