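sex,age_group,state,prevalence_percent
male,55-59,ADV,6.6
male,60-64,ADV,8.2
male,65-69,ADV,9.2
male,70-74,ADV,9.9
male,75-79,ADV,10.4
male,55-59,CRC,0.60
male,60-64,CRC,1.00
male,65-69,CRC,1.30
male,70-74,CRC,1.90
male,75-79,CRC,2.50
male,AGG,ADV,8.86
male,AGG,CRC,1.46
female,55-59,ADV,3.50
female,60-64,ADV,4.50
female,65-69,ADV,5.30
female,70-74,ADV,6.40
female,75-79,ADV,6.80
female,55-59,CRC,0.30
female,60-64,CRC,0.50
female,65-69,CRC,0.70
female,70-74,CRC,1.10
female,75-79,CRC,1.60
female,AGG,ADV,5.30
female,AGG,CRC,0.84
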