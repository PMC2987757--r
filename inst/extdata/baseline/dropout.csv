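specialty_id,sex,age,rate
1,female,30,0.0060000000000000001
2,female,30,0.0060000000000000001
3,female,30,0.0060000000000000001
1,male,30,0.0030000000000000001
2,male,30,0.0030000000000000001
3,male,30,0.0030000000000000001
1,female,31,0.0060000000000000001
2,female,31,0.0060000000000000001
3,female,31,0.0060000000000000001
1,male,31,0.0030000000000000001
2,male,31,0.0030000000000000001
3,male,31,0.0030000000000000001
1,female,32,0.0060000000000000001
2,female,32,0.0060000000000000001
3,female,32,0.0060000000000000001
1,male,32,0.0030000000000000001
2,male,32,0.0030000000000000001
3,male,32,0.0030000000000000001
1,female,33,0.0060000000000000001
2,female,33,0.0060000000000000001
3,female,33,0.0060000000000000001
1,male,33,0.0030000000000000001
2,male,33,0.0030000000000000001
3,male,33,0.0030000000000000001
1,female,34,0.0060000000000000001
2,female,34,0.0060000000000000001
3,female,34,0.0060000000000000001
1,male,34,0.0030000000000000001
2,male,34,0.0030000000000000001
3,male,34,0.0030000000000000001
1,female,35,0.0060000000000000001
2,female,35,0.0060000000000000001
3,female,35,0.0060000000000000001
1,male,35,0.0030000000000000001
2,male,35,0.0030000000000000001
3,male,35,0.0030000000000000001
1,female,36,0.0060000000000000001
2,female,36,0.0060000000000000001
3,female,36,0.0060000000000000001
1,male,36,0.0030000000000000001
2,male,36,0.0030000000000000001
3,male,36,0.0030000000000000001
1,female,37,0.0060000000000000001
2,female,37,0.0060000000000000001
3,female,37,0.0060000000000000001
1,male,37,0.0030000000000000001
2,male,37,0.0030000000000000001
3,male,37,0.0030000000000000001
1,female,38,0.0060000000000000001
2,female,38,0.0060000000000000001
3,female,38,0.0060000000000000001
1,male,38,0.0030000000000000001
2,male,38,0.0030000000000000001
3,male,38,0.0030000000000000001
1,female,39,0.0060000000000000001
2,female,39,0.0060000000000000001
3,female,39,0.0060000000000000001
1,male,39,0.0030000000000000001
2,male,39,0.0030000000000000001
3,male,39,0.0030000000000000001
1,female,40,0.0060000000000000001
2,female,40,0.0060000000000000001
3,female,40,0.0060000000000000001
1,male,40,0.0030000000000000001
2,male,40,0.0030000000000000001
3,male,40,0.0030000000000000001
1,female,41,0.0060000000000000001
2,female,41,0.0060000000000000001
3,female,41,0.0060000000000000001
1,male,41,0.0030000000000000001
2,male,41,0.0030000000000000001
3,male,41,0.0030000000000000001
1,female,42,0.0060000000000000001
2,female,42,0.0060000000000000001
3,female,42,0.0060000000000000001
1,male,42,0.0030000000000000001
2,male,42,0.0030000000000000001
3,male,42,0.0030000000000000001
1,female,43,0.0060000000000000001
2,female,43,0.0060000000000000001
3,female,43,0.0060000000000000001
1,male,43,0.0030000000000000001
2,male,43,0.0030000000000000001
3,male,43,0.0030000000000000001
1,female,44,0.0060000000000000001
2,female,44,0.0060000000000000001
3,female,44,0.0060000000000000001
1,male,44,0.0030000000000000001
2,male,44,0.0030000000000000001
3,male,44,0.0030000000000000001
1,female,45,0.0060000000000000001
2,female,45,0.0060000000000000001
3,female,45,0.0060000000000000001
1,male,45,0.0030000000000000001
2,male,45,0.0030000000000000001
3,male,45,0.0030000000000000001
1,female,46,0.0060000000000000001
2,female,46,0.0060000000000000001
3,female,46,0.0060000000000000001
1,male,46,0.0030000000000000001
2,male,46,0.0030000000000000001
3,male,46,0.0030000000000000001
1,female,47,0.0060000000000000001
2,female,47,0.0060000000000000001
3,female,47,0.0060000000000000001
1,male,47,0.0030000000000000001
2,male,47,0.0030000000000000001
3,male,47,0.0030000000000000001
1,female,48,0.0060000000000000001
2,female,48,0.0060000000000000001
3,female,48,0.0060000000000000001
1,male,48,0.0030000000000000001
2,male,48,0.0030000000000000001
3,male,48,0.0030000000000000001
1,female,49,0.0060000000000000001
2,female,49,0.0060000000000000001
3,female,49,0.0060000000000000001
1,male,49,0.0030000000000000001
2,male,49,0.0030000000000000001
3,male,49,0.0030000000000000001
1,female,50,0.0060000000000000001
2,female,50,0.0060000000000000001
3,female,50,0.0060000000000000001
1,male,50,0.0030000000000000001
2,male,50,0.0030000000000000001
3,male,50,0.0030000000000000001
1,female,51,0.0060000000000000001
2,female,51,0.0060000000000000001
3,female,51,0.0060000000000000001
1,male,51,0.0030000000000000001
2,male,51,0.0030000000000000001
3,male,51,0.0030000000000000001
1,female,52,0.0060000000000000001
2,female,52,0.0060000000000000001
3,female,52,0.0060000000000000001
1,male,52,0.0030000000000000001
2,male,52,0.0030000000000000001
3,male,52,0.0030000000000000001
1,female,53,0.0060000000000000001
2,female,53,0.0060000000000000001
3,female,53,0.0060000000000000001
1,male,53,0.0030000000000000001
2,male,53,0.0030000000000000001
3,male,53,0.0030000000000000001
1,female,54,0.0060000000000000001
2,female,54,0.0060000000000000001
3,female,54,0.0060000000000000001
1,male,54,0.0030000000000000001
2,male,54,0.0030000000000000001
3,male,54,0.0030000000000000001
1,female,55,0.0060000000000000001
2,female,55,0.0060000000000000001
3,female,55,0.0060000000000000001
1,male,55,0.0030000000000000001
2,male,55,0.0030000000000000001
3,male,55,0.0030000000000000001
1,female,56,0.0060000000000000001
2,female,56,0.0060000000000000001
3,female,56,0.0060000000000000001
1,male,56,0.0030000000000000001
2,male,56,0.0030000000000000001
3,male,56,0.0030000000000000001
1,female,57,0.0060000000000000001
2,female,57,0.0060000000000000001
3,female,57,0.0060000000000000001
1,male,57,0.0030000000000000001
2,male,57,0.0030000000000000001
3,male,57,0.0030000000000000001
1,female,58,0.0060000000000000001
2,female,58,0.0060000000000000001
3,female,58,0.0060000000000000001
1,male,58,0.0030000000000000001
2,male,58,0.0030000000000000001
3,male,58,0.0030000000000000001
1,female,59,0.0060000000000000001
2,female,59,0.0060000000000000001
3,female,59,0.0060000000000000001
1,male,59,0.0030000000000000001
2,male,59,0.0030000000000000001
3,male,59,0.0030000000000000001
1,female,60,0.0060000000000000001
2,female,60,0.0060000000000000001
3,female,60,0.0060000000000000001
1,male,60,0.0030000000000000001
2,male,60,0.0030000000000000001
3,male,60,0.0030000000000000001
1,female,61,0.0060000000000000001
2,female,61,0.0060000000000000001
3,female,61,0.0060000000000000001
1,male,61,0.0030000000000000001
2,male,61,0.0030000000000000001
3,male,61,0.0030000000000000001
1,female,62,0.0060000000000000001
2,female,62,0.0060000000000000001
3,female,62,0.0060000000000000001
1,male,62,0.0030000000000000001
2,male,62,0.0030000000000000001
3,male,62,0.0030000000000000001
1,female,63,0.0060000000000000001
2,female,63,0.0060000000000000001
3,female,63,0.0060000000000000001
1,male,63,0.0030000000000000001
2,male,63,0.0030000000000000001
3,male,63,0.0030000000000000001
1,female,64,0.0060000000000000001
2,female,64,0.0060000000000000001
3,female,64,0.0060000000000000001
1,male,64,0.0030000000000000001
2,male,64,0.0030000000000000001
3,male,64,0.0030000000000000001
1,female,65,0.0060000000000000001
2,female,65,0.0060000000000000001
3,female,65,0.0060000000000000001
1,male,65,0.0030000000000000001
2,male,65,0.0030000000000000001
3,male,65,0.0030000000000000001
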