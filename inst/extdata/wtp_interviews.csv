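participant_id,role,wtp_gbp,qualitative_code
A1,adult,200,
A2,adult,2000,
A3,adult,5000,
P1,parent,,would pay but cannot quantify
P2,parent,500,
P3,parent,5000,
P4,parent,,willing to pay if child's quality of life improved
P5,parent,2000,
P6,parent,1000,
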