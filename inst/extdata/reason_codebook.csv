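code,reason,group
1,diabetes,NCD
2,heart disease or high blood pressure,NCD
3,stroke,NCD
4,cancer,NCD
5,chronic lung disease or asthma,NCD
6,depression or anxiety,NCD
7,fever or malaria,CD
8,tuberculosis,CD
9,diarrhoea,CD
10,childbirth or delivery,CD
11,antenatal or postnatal care,CD
12,child illness or immunization,CD
13,road traffic injury,INJURY
14,other injury,INJURY
15,back or joint pain,PAIN
16,planned surgery,SURGERY
17,routine check-up or other,OTHER
18,do not know,UNIDENTIFIED
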