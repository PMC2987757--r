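sex,age,rate
female,30,0.00040000000000000002
male,30,0.00050000000000000001
female,31,0.00043766971348208419
male,31,0.00054708714185260521
female,32,0.00047888694524872411
male,32,0.00059860868156090508
female,33,0.00052398578029329897
male,33,0.00065498222536662372
female,34,0.00057333176582413604
male,34,0.00071666470728017008
female,35,0.00062732487419606749
male,35,0.00078415609274508434
female,36,0.00068640274487394347
male,36,0.00085800343109242931
female,37,0.00075104423170573725
male,37,0.00093880528963217157
female,38,0.00082177328425755514
male,38,0.0010272166053219439
female,39,0.00089916319467058859
male,39,0.0011239539933382357
female,40,0.00098384124446277972
male,40,0.0012298015555784747
female,41,0.0010764937889397048
male,41,0.001345617236174631
female,42,0.0011778718204262099
male,42,0.0014723397755327622
female,43,0.0012887970554113998
male,43,0.0016109963192642498
female,44,0.0014101685949461529
male,44,0.0017627107436826912
female,45,0.0015429702122787897
male,45,0.001928712765348487
female,46,0.0016882783267986208
male,46,0.002110347908498276
female,47,0.0018472707289199125
male,47,0.0023090884111498905
female,48,0.0020212361266255469
male,48,0.0025265451582819334
female,49,0.002211584591049602
male,49,0.0027644807388120022
female,50,0.0024198589857651782
male,50,0.0030248237322064724
female,51,0.002647747472417231
male,51,0.0033096843405215383
female,52,0.0028970971940644051
male,52,0.0036213714925805063
female,53,0.0031699292471397949
male,53,0.0039624115589247432
female,54,0.0034684550633853825
male,54,0.0043355688292317281
female,55,0.0037950943345434109
male,55,0.0047438679181792632
female,56,0.0041524946250927368
male,56,0.0051906182813659212
female,57,0.0045435528320005815
male,57,0.005679441040000727
female,58,0.0049714386654310175
male,58,0.0062142983317887718
female,59,0.0054396203407323703
male,59,0.0067995254259154625
female,60,0.0059518926899491328
male,60,0.0074398658624364152
female,61,0.0065124079207153716
male,61,0.008140509900894214
female,62,0.00712570927184488
male,62,0.0089071365898060993
female,63,0.0077967678384124458
male,63,0.0097459597980155566
female,64,0.0085310228648107621
male,64,0.010663778581013451
female,65,0.0093344258323770843
male,65,0.011668032290471355
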