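sex,age,ratio
female,30,0.90000000000000002
male,30,1
female,31,0.90000000000000002
male,31,1
female,32,0.90000000000000002
male,32,1
female,33,0.90000000000000002
male,33,1
female,34,0.90000000000000002
male,34,1
female,35,0.90000000000000002
male,35,1
female,36,0.90000000000000002
male,36,1
female,37,0.90000000000000002
male,37,1
female,38,0.90000000000000002
male,38,1
female,39,0.90000000000000002
male,39,1
female,40,0.90000000000000002
male,40,1
female,41,0.90000000000000002
male,41,1
female,42,0.90000000000000002
male,42,1
female,43,0.90000000000000002
male,43,1
female,44,0.90000000000000002
male,44,1
female,45,0.90000000000000002
male,45,1
female,46,0.90000000000000002
male,46,1
female,47,0.90000000000000002
male,47,1
female,48,0.90000000000000002
male,48,1
female,49,0.90000000000000002
male,49,1
female,50,0.90000000000000002
male,50,1
female,51,0.90000000000000002
male,51,1
female,52,0.90000000000000002
male,52,1
female,53,0.90000000000000002
male,53,1
female,54,0.90000000000000002
male,54,1
female,55,0.90000000000000002
male,55,1
female,56,0.90000000000000002
male,56,1
female,57,0.90000000000000002
male,57,1
female,58,0.90000000000000002
male,58,1
female,59,0.90000000000000002
male,59,1
female,60,0.90000000000000002
male,60,1
female,61,0.90000000000000002
male,61,1
female,62,0.90000000000000002
male,62,1
female,63,0.90000000000000002
male,63,1
female,64,0.90000000000000002
male,64,1
female,65,0.90000000000000002
male,65,1
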