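tf	target	peak_intensity	regulatory_potential
TF1	SW_1	120	0.2
TF1	SW_2	80	0.4
TF1	SW_3	60	0.1
TF2	SW_1	499.9	0.99
TF2	SW_2	600	0.2
TF3	SW_3	100	1.0
TF3	SW_4	90	0.5
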