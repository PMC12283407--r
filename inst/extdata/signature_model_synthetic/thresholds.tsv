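signature	threshold
CX1	0.0114
CX2	0.0209
CX3	0.0289
CX4	0.0188
CX5	0.0296
CX6	0.0178
CX7	0.0283
CX8	0.0157
CX9	0.0171
CX10	0.0145
CX11	0.0273
CX12	0.0091
CX13	0.0169
CX14	0.0263
CX15	0.0264
CX16	0.0235
CX17	0.0138
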