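patient_id,age,bmi,dm_duration,microvascular,macrovascular,insulin_use,c_peptide_stim,hba1c,procedure,on_medication,remission
P001,45,30.2,5,no,no,no,5.1,8.4,IISG,yes,1
P002,52,24.1,12,yes,no,yes,3.2,9.1,IISG,yes,0
P003,38,28.6,3,no,no,no,4.4,7.6,IISG,yes,1
P004,64,22.0,15,yes,yes,yes,2.1,9.8,IIDSG,yes,0
P005,57,27.5,8,no,no,yes,3.8,8.9,IIDSG,yes,1
P006,29,31.0,2,no,no,no,4.9,7.9,IISG,yes,1
P007,61,25.3,11,yes,no,yes,2.8,9.4,IIDSG,yes,0
P008,48,21.7,9,no,no,no,3.6,8.2,IISG,yes,1
P009,55,29.8,14,yes,yes,yes,1.9,10.2,IIDSG,yes,0
P010,42,26.4,6,no,no,yes,4.2,8.7,IISG,yes,0
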