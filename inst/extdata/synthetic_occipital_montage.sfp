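Oz	0	-9.7	-0.4
POz	0	-8.9	2.6
L01	-1.691	-9.494	-0.591
L02	-3.101	-9.656	-2.001
L03	-4.511	-9.818	-3.411
L04	-2.426	-9.504	0.45
L05	-4.352	-9.666	-0.066
L06	-6.277	-9.828	-0.582
L07	-2.542	-9.514	1.781
L08	-4.467	-9.676	2.297
L09	-6.393	-9.838	2.813
L10	-1.945	-9.523	3.045
L11	-3.355	-9.685	4.455
L12	-4.764	-9.847	5.864
R01	1.691	-9.494	-0.591
R02	3.101	-9.656	-2.001
R03	4.511	-9.818	-3.411
R04	2.426	-9.504	0.45
R05	4.352	-9.666	-0.066
R06	6.277	-9.828	-0.582
R07	2.542	-9.514	1.781
R08	4.467	-9.676	2.297
R09	6.393	-9.838	2.813
R10	1.945	-9.523	3.045
R11	3.355	-9.685	4.455
R12	4.764	-9.847	5.864
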