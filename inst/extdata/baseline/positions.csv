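specialty_id,year,positions
1,2008,250
2,2008,250
3,2008,250
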