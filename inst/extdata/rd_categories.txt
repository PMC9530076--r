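intellectual disability
neurodevelopmental and neurological disorders without intellectual disability
cardiovascular disorders
ciliopathies
dermatological disorders
dysmorphic and congenital abnormality syndromes
endocrine disorders
gastroenterological disorders
genomic medicine service indications
growth disorders
haematological and immunological disorders
hearing and ear disorders
metabolic disorders
neuromuscular disorders
ophthalmological disorders
renal and urinary tract disorders
respiratory disorders
skeletal disorders
tumour syndromes
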