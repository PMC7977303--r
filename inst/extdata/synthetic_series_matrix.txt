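!Series_title	"Synthetic kidney allograft expression fixture (not real GEO data)"
!Series_geo_accession	"GSE00000"
!Series_platform_id	"GPL570"
!Sample_title	"biopsy 1"	"biopsy 2"	"biopsy 3"	"biopsy 4"	"biopsy 5"	"biopsy 6"
!Sample_geo_accession	"GSM000001"	"GSM000002"	"GSM000003"	"GSM000004"	"GSM000005"	"GSM000006"
!Sample_characteristics_ch1	"diagnosis: TCMR"	"diagnosis: ABMR"	"diagnosis: no rejection"	"diagnosis: no rejection"	"diagnosis: ATN"	"diagnosis: nephrectomy"
!Sample_characteristics_ch1	"tissue: kidney biopsy"	"tissue: kidney biopsy"	"tissue: kidney biopsy"	"tissue: kidney biopsy"	"tissue: kidney biopsy"	"tissue: kidney biopsy"
!series_matrix_table_begin
"ID_REF"	"GSM000001"	"GSM000002"	"GSM000003"	"GSM000004"	"GSM000005"	"GSM000006"
"1001_at"	210.5	180.2	150.1	148.9	160.3	155.7
"1002_a_at"	96.4	101.2	99.8	98.1	102.5	97.3
"1003_s_at"	300.7	420.9	140.2	135.8	150.4	120.6
"1004_x_at"	88.1	90.4	91.2	89.5	92.3	90.8
"1005_at"	512.3	140.6	130.9	128.4	133.2	125.1
"1006_at"	75.2	78.9	80.4	77.1	260.8	79.5
"1007_s_at"	150.9	149.2	151.8	148.6	150.2	310.4
"1008_at"	60.3	61.8	59.4	62.1	60.9	61.2
!series_matrix_table_end
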