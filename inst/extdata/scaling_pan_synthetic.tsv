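signature	mean	sd
CX1	0.0355	0.0268
CX2	0.1168	0.0439
CX3	0.0668	0.0387
CX4	0.0977	0.0547
CX5	0.0608	0.0423
CX6	0.0739	0.0483
CX7	0.0407	0.0511
CX8	0.0387	0.0556
CX9	0.098	0.0192
CX10	0.0394	0.0409
CX11	0.0634	0.0409
CX12	0.0202	0.0575
CX13	0.1035	0.0249
CX14	0.103	0.0365
CX15	0.1157	0.017
CX16	0.1148	0.051
CX17	0.0801	0.0316
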