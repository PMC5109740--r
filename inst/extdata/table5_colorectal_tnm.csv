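Specimen,Invasion of,rLN,tp rLN,TD/ Sat.,dMT,ip dMT,T_P,N_P,M_P
1,Subserosa,31,0,no,0,no,pT3,pN0,M0
2,Muscular layer,13,0,no,0,no,pT2,pN0,M0
3,Subserosa,19,0,no,0,no,pT3,pN0,M0
4,Submucosa,18,0,no,0,no,pT1,pN0,M0
5,Muscular layer,11,0,no,0,no,pT2,pN0,M0
6,Visc. peritoneum,19,2,no,0,no,pT4a,pN1b,M0
7,Subserosa,20,0,yes,0,no,pT3,pN1c,M0
8,Subserosa,14,2,no,0,no,pT3,pN1b,M0
9,Muscular layer,14,0,no,0,no,pT2,pN0,M0
10,Subserosa,24,4,no,0,no,pT3,pN2a,M0
11,Other,16,6,no,0,no,pT4b,pN2a,M0
12,Subserosa,17,0,no,0,no,pT3,pN0,M0
13,Visc. peritoneum,40,29,no,0,no,pT4a,pN2b,M0
14,Subserosa,15,0,no,0,no,pT3,pN0,M0
15,Visc. peritoneum,24,15,no,1,no,pT4a,pN2b,M1a
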