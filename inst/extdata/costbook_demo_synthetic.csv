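test_name,test_class,amplicon_count,cost_gbp,price_year,tier
MECP2 sequencing,single_gene,4,420.00,2018,scotland_lab
MECP2 sequencing,single_gene,4,500.00,2018,uk_lab
FBN1 sequencing,single_gene,66,912.50,2018,scotland_lab
SCN1A sequencing,single_gene,26,610.00,2018,uk_lab
PTPN11 sequencing,single_gene,15,480.00,2018,scotland_lab
UBE3A methylation,epigenetic,8,240.00,2018,scotland_lab
SNRPN methylation,epigenetic,6,255.00,2017,scotland_lab
Epilepsy gene panel,gene_panel,104,1250.00,2018,scotland_lab
Cardiac gene panel,gene_panel,92,1390.00,2016,uk_lab
Skeletal dysplasia panel,gene_panel,55,980.00,2018,scotland_lab
Microarray CGH,first_line,,395.00,2018,scotland_lab
Karyotype,first_line,,180.00,2018,scotland_lab
FISH 15q11,first_line,,150.00,2018,uk_lab
DMD deletion analysis,single_gene,79,540.00,2018,scotland_lab
GJB2 sequencing,single_gene,2,90.00,2018,scotland_lab
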