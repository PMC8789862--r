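e1	e2
Fp1	F7
F7	T3
T3	T5
T5	O1
Fp1	F3
F3	C3
C3	P3
P3	O1
Fz	Cz
Cz	Pz
Fp2	F8
F8	T4
T4	T6
T6	O2
Fp2	F4
F4	C4
C4	P4
P4	O2
A1	T3
A2	T4
F3	Fz
F4	Fz
C3	Fz
C4	Fz
C3	Pz
C4	Pz
P3	Pz
P4	Pz
T5	C3
T6	C4
F7	F3
F8	F4
T5	P3
T6	P4
Fp1	Fp2
O1	O2
Fp1	Fz
Fp2	Fz
O1	Pz
O2	Pz
A1	T5
A2	T6
T3	F3
T4	F4
T3	P3
T4	P4
F7	Fz
F8	Fz
T5	Pz
T6	Pz
A1	F7
A2	F8
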