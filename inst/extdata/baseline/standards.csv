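specialty_id,base_ratio_per_100k,demand_group
1,3.8317343881391861,stable
2,3.8317343881391861,stable_increasing
3,3.8317343881391861,sharply_increasing
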