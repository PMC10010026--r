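study_id,t_cases,t_n,c_cases,c_n
T01,12,120,5,118
T02,8,90,3,88
T03,10,150,4,145
T04,6,75,2,70
T05,5,60,2,64
T06,9,110,4,105
T07,4,55,1,50
T08,7,85,3,80
T09,3,40,1,42
T10,0,35,2,33
T11,2,45,0,44
T12,0,28,1,30
T13,1,50,0,48
T14,3,66,0,62
T15,0,25,1,24
T16,2,38,0,40
T17,1,30,0,32
T18,0,42,1,40
T19,0,52,0,50
T20,0,36,0,34
T21,0,20,0,22
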