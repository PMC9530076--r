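proband_id,category,test_name,amplicon_count
D001,intellectual disability,Microarray CGH,
D001,intellectual disability,MECP2 sequencing,
D001,intellectual disability,UBE3A methylation,
D002,neurodevelopmental and neurological disorders without intellectual disability,Epilepsy gene panel,
D002,neurodevelopmental and neurological disorders without intellectual disability,SCN1A sequencing,
D003,cardiovascular disorders,Cardiac gene panel,
D004,intellectual disability,Karyotype,
D004,intellectual disability,FISH 15q11,
D004,intellectual disability,SNRPN methylation,
D005,skeletal disorders,Skeletal dysplasia panel,
D005,skeletal disorders,FGFR3 sequencing,7
D006,hearing and ear disorders,GJB2 sequencing,
D007,neuromuscular disorders,DMD deletion analysis,
D007,neuromuscular disorders,illegible handwritten test,
D008,intellectual disability,MECP2 sequencing,
D008,intellectual disability,Epilepsy gene panel,
D008,intellectual disability,SCN1A sequencing,
D008,intellectual disability,UBE3A methylation,
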