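participant_id,attribute,score
A1,chance_of_diagnosis,5
A1,waiting_time,5
A1,family_information,5
A1,other_conditions_information,5
A1,research_contribution,5
A2,chance_of_diagnosis,5
A2,waiting_time,3
A2,family_information,4
A2,other_conditions_information,4
A2,research_contribution,5
A3,chance_of_diagnosis,5
A3,waiting_time,5
A3,family_information,5
A3,other_conditions_information,5
A3,research_contribution,5
P1,chance_of_diagnosis,5
P1,waiting_time,4
P1,family_information,5
P1,other_conditions_information,3
P1,research_contribution,4
P2,chance_of_diagnosis,4
P2,waiting_time,4
P2,family_information,5
P2,other_conditions_information,4
P2,research_contribution,3
P3,chance_of_diagnosis,5
P3,waiting_time,5
P3,family_information,5
P3,other_conditions_information,5
P3,research_contribution,5
P4,chance_of_diagnosis,5
P4,waiting_time,3
P4,family_information,5
P4,other_conditions_information,5
P4,research_contribution,4
P5,chance_of_diagnosis,5
P5,waiting_time,5
P5,family_information,5
P5,other_conditions_information,5
P5,research_contribution,5
P6,chance_of_diagnosis,4
P6,waiting_time,5
P6,family_information,4
P6,other_conditions_information,5
P6,research_contribution,5
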