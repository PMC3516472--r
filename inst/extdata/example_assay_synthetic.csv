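line,fitness,treatment,subline,rep,gmax,d1,d2,d3,s1,s2,s3
L01,high,control,P01,R1,0,64,39,10,TRUE,TRUE,TRUE
L01,high,control,P01,R2,0,55,44,15,TRUE,TRUE,TRUE
L01,high,control,P01,R3,0,42,23,3,TRUE,TRUE,TRUE
L01,high,control,P02,R1,0,15,8,1,TRUE,TRUE,TRUE
L01,high,control,P02,R2,0,47,34,11,TRUE,TRUE,TRUE
L01,high,control,P02,R3,0,41,37,7,TRUE,TRUE,TRUE
L01,high,control,P03,R1,0,0,0,0,TRUE,TRUE,TRUE
L01,high,control,P03,R2,0,0,0,0,TRUE,TRUE,TRUE
L01,high,control,P03,R3,0,34,14,5,TRUE,TRUE,TRUE
L01,high,control,P04,R1,0,71,46,13,TRUE,TRUE,TRUE
L01,high,control,P04,R2,0,38,21,8,TRUE,TRUE,TRUE
L01,high,control,P04,R3,0,174,101,27,TRUE,TRUE,TRUE
L01,high,ma,S01,R1,150,56,36,5,TRUE,TRUE,TRUE
L01,high,ma,S01,R2,150,222,102,34,TRUE,TRUE,TRUE
L01,high,ma,S01,R3,150,56,30,13,TRUE,TRUE,TRUE
L01,high,ma,S02,R1,150,152,87,31,TRUE,TRUE,TRUE
L01,high,ma,S02,R2,150,65,50,9,TRUE,TRUE,TRUE
L01,high,ma,S02,R3,150,48,33,13,TRUE,TRUE,TRUE
L01,high,ma,S03,R1,150,54,38,6,TRUE,TRUE,TRUE
L01,high,ma,S03,R2,150,141,104,26,TRUE,TRUE,TRUE
L01,high,ma,S03,R3,150,25,22,6,TRUE,TRUE,TRUE
L01,high,ma,S04,R1,150,37,14,7,TRUE,TRUE,TRUE
L01,high,ma,S04,R2,150,189,102,28,TRUE,TRUE,TRUE
L01,high,ma,S04,R3,150,0,0,0,TRUE,TRUE,TRUE
L01,high,ma,S05,R1,150,28,10,3,TRUE,TRUE,TRUE
L01,high,ma,S05,R2,150,150,127,27,TRUE,TRUE,TRUE
L01,high,ma,S05,R3,150,138,77,21,TRUE,TRUE,TRUE
L02,low,control,P01,R1,0,31,26,6,TRUE,TRUE,TRUE
L02,low,control,P01,R2,0,58,33,10,TRUE,TRUE,TRUE
L02,low,control,P01,R3,0,145,89,31,TRUE,TRUE,TRUE
L02,low,control,P02,R1,0,72,67,14,TRUE,TRUE,TRUE
L02,low,control,P02,R2,0,133,67,14,TRUE,TRUE,TRUE
L02,low,control,P02,R3,0,46,24,7,TRUE,TRUE,TRUE
L02,low,control,P03,R1,0,78,51,11,TRUE,TRUE,TRUE
L02,low,control,P03,R2,0,0,0,0,TRUE,TRUE,TRUE
L02,low,control,P03,R3,0,87,58,18,TRUE,TRUE,TRUE
L02,low,control,P04,R1,0,51,44,6,TRUE,TRUE,TRUE
L02,low,control,P04,R2,0,81,42,10,TRUE,TRUE,TRUE
L02,low,control,P04,R3,0,65,36,10,TRUE,TRUE,TRUE
L02,low,ma,S01,R1,150,78,58,13,TRUE,TRUE,TRUE
L02,low,ma,S01,R2,150,24,6,4,TRUE,TRUE,TRUE
L02,low,ma,S01,R3,150,35,17,8,TRUE,TRUE,TRUE
L02,low,ma,S02,R1,150,64,51,12,TRUE,TRUE,TRUE
L02,low,ma,S02,R2,150,66,45,11,TRUE,TRUE,TRUE
L02,low,ma,S02,R3,150,52,42,10,TRUE,TRUE,TRUE
L02,low,ma,S03,R1,150,60,48,18,TRUE,TRUE,TRUE
L02,low,ma,S03,R2,150,24,17,7,TRUE,TRUE,TRUE
L02,low,ma,S03,R3,150,62,39,11,TRUE,TRUE,TRUE
L02,low,ma,S04,R1,150,57,29,8,TRUE,TRUE,TRUE
L02,low,ma,S04,R2,150,86,61,16,TRUE,TRUE,TRUE
L02,low,ma,S04,R3,150,0,0,0,TRUE,TRUE,TRUE
L02,low,ma,S05,R1,150,33,23,5,TRUE,TRUE,TRUE
L02,low,ma,S05,R2,150,40,17,10,TRUE,TRUE,TRUE
L02,low,ma,S05,R3,150,24,19,5,TRUE,TRUE,TRUE
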