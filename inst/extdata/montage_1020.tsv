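label	x	y
Fp1	-0.31	0.95
Fp2	0.31	0.95
F7	-0.81	0.59
F3	-0.43	0.55
Fz	0.00	0.52
F4	0.43	0.55
F8	0.81	0.59
T3	-1.00	0.00
C3	-0.50	0.00
Cz	0.00	0.00
C4	0.50	0.00
T4	1.00	0.00
T5	-0.81	-0.59
P3	-0.43	-0.55
Pz	0.00	-0.52
P4	0.43	-0.55
T6	0.81	-0.59
O1	-0.31	-0.95
O2	0.31	-0.95
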