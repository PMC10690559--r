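patient_id,age,sex,blood_volume_l,mutation,relapse,risk_group,n_ctdna_measurements,n_blast_measurements
N1,28,female,4.0,NPM1,FALSE,Intermediate,9,2
N2,36,female,4.7,NPM1,FALSE,Favorable,2,2
N3,46,female,3.6,NPM1,FALSE,Intermediate,9,2
N4,52,female,4.5,NPM1,FALSE,Favorable,7,2
N5,59,male,5.9,NPM1,FALSE,Favorable,5,2
N6,60,female,4.2,NPM1,FALSE,Favorable,12,2
N7,67,male,5.1,NPM1,TRUE,Favorable,12,1
I1,55,female,4.6,IDH2,FALSE,Intermediate,14,2
I2,67,male,5.1,IDH2,TRUE,Intermediate,6,2
I3,68,male,5.6,IDH2,TRUE,Adverse,11,2
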