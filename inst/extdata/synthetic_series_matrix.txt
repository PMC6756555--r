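!Series_title	"synthetic three-probe example (hand-made, not from any accession)"
!Series_geo_accession	"SYNTHETIC"
!Sample_title	"ctrl1"	"ctrl2"	"case1"	"case2"
!series_matrix_table_begin
"ID_REF"	"S1"	"S2"	"S3"	"S4"
"P1"	7.1	7.3	8.0	8.2
"P2"	5.0	5.1	5.2	5.3
"P3"	9.5	9.4	2.0	2.1
!series_matrix_table_end
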