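# Trio WGS stage configuration: 13-stage pathway of a Scottish regional
# genetics centre, 2018 prices, NHS Scotland perspective.
#
# Stages whose internal composition (staff rates, consumable prices) is not
# public carry method `calibrated`: the per-trio value is the stage total
# from the centre's micro-costing exercise. External charges carry method
# `charge`; sequencing is stored net (850/sample x 3 samples) with VAT
# added at costing time, data analysis and storage are VAT-inclusive
# pass-through charges.
stages:
  - name: "Screening and recruitment"
    method: calibrated
    cost_per_trio: 132.63
    assumptions: "Screening and recruitment undertaken by regional genetics centres"
  - name: "Consent and obtaining blood sample for DNA extraction"
    method: calibrated
    cost_per_trio: 96.42
    assumptions: "40% of probands did not require a new sample; 75% of probands requiring a new sample needed a separate hospital visit"
  - name: "Phenotyping"
    method: calibrated
    cost_per_trio: 58.17
    assumptions: "Phenotype data entered into the study database per protocol"
  - name: "Sample reception"
    method: calibrated
    cost_per_trio: 8.80
    assumptions: "Sample reception and book-in at regional genetics laboratory"
  - name: "DNA extraction"
    method: calibrated
    cost_per_trio: 186.88
    assumptions: "Batch size of 24 samples"
  - name: "Sample send-away"
    method: calibrated
    cost_per_trio: 30.00
    assumptions: "Batch size 3 (one trio)"
  - name: "Sequencing of DNA"
    method: charge
    charge_per_trio: 2550.00
    vat_applies: true
    assumptions: "Charged per trio by the sequencing centre; 850/sample net of VAT"
  - name: "Data analysis"
    method: charge
    charge_per_trio: 1684.00
    assumptions: "Charged per trio by the national analysis provider; includes encrypted FASTQ transfer, variant-call and BAM generation, bioinformatic analysis and return of results"
  - name: "Data storage"
    method: charge
    charge_per_trio: 540.00
    assumptions: "Charged per trio by the national analysis provider"
  - name: "Variant interpretation"
    method: calibrated
    cost_per_trio: 305.24
    assumptions: "Average of 4 variants per case (trio-based analysis, exonic variants); no additional testing to aid classification"
  - name: "Variant validation"
    method: calibrated
    cost_per_trio: 296.87
    assumptions: "Potentially pathogenic variants confirmed by Sanger sequencing; assumed annual throughput 100 samples (33 trios)"
  - name: "MDT meeting to discuss findings"
    method: calibrated
    cost_per_trio: 67.99
    assumptions: "50% of cases require an MDT meeting; time per case 5-20 min"
  - name: "Patient feedback"
    method: calibrated
    cost_per_trio: 158.20
    assumptions: "All cases assumed to receive feedback at a genetics clinic appointment"
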