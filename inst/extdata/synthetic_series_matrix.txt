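!Series_title	"Synthetic series-matrix fixture (not real GEO data)"
!Series_geo_accession	"GSE00000"
!Sample_title	"sample A"	"sample B"
!Sample_geo_accession	"GSM000001"	"GSM000002"
!Sample_characteristics_ch1	"tissue: whole blood"	"tissue: whole blood"
!Sample_characteristics_ch1	"age: 34"	"age: 67"
!Sample_characteristics_ch1	"gender: F"	"gender: M"
!series_matrix_table_begin
"ID_REF"	"GSM000001"	"GSM000002"
"cg00000001"	0.12	0.34
"cg00000002"	0.55	0.61
"cg00000003"	0.90	0.88
!series_matrix_table_end
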