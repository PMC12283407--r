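signature	mean	sd
CX1	0.1023	0.0169
CX2	0.091	0.0573
CX3	0.1166	0.018
CX4	0.0279	0.0163
CX5	0.0254	0.0209
CX6	0.0775	0.0519
CX7	0.0588	0.0554
CX8	0.071	0.0193
CX9	0.0566	0.0463
CX10	0.0418	0.0383
CX11	0.0843	0.0349
CX12	0.0953	0.0247
CX13	0.0292	0.0295
CX14	0.0507	0.0549
CX15	0.1192	0.0372
CX16	0.0319	0.023
CX17	0.0725	0.0241
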