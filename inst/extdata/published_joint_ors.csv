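section,outcome,exposure,model,or01,or10,or11,reri_printed,ap_printed,s_printed,consistent
1A,self_reported_diabetes,self_reported_ht,unadjusted,5.93,4.00,17.63,8.69,0.49,2.09,TRUE
1B,self_reported_diabetes,ht_on_medication,unadjusted,6.34,3.55,19.57,10.68,0.55,2.35,TRUE
2A,diabetes_on_medication,self_reported_ht,unadjusted,5.56,3.92,18.11,8.68,0.49,2.09,FALSE
2B,diabetes_on_medication,ht_on_medication,unadjusted,7.58,3.65,24.73,14.50,0.59,2.57,TRUE
1A,self_reported_diabetes,self_reported_ht,adjusted,4.21,2.82,9.28,3.50,0.37,1.69,TRUE
1B,self_reported_diabetes,ht_on_medication,adjusted,4.07,2.60,9.46,3.79,0.40,1.81,TRUE
2A,diabetes_on_medication,self_reported_ht,adjusted,3.73,2.53,8.50,3.24,0.38,1.76,TRUE
2B,diabetes_on_medication,ht_on_medication,adjusted,4.74,2.46,11.11,4.91,0.44,1.94,TRUE
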