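PATH_A	synthetic set A	M1_G1	M1_G2	M1_G3	M1_G4	SW_1
PATH_B	synthetic set B	M2_G1	M2_G2	M2_G3	SW_1	SW_2
PATH_C	synthetic set C	NOISE_1	NOISE_2	NOISE_3
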