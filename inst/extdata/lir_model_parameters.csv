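parameter,estimate,se,ci_lower,ci_upper
N,13.0665,1.667,10.768,16.777
mean_time_in_days,13.9501,1.186,13.102,16.577
mean_time_out_days,21.7136,2.316,16.468,24.743
mortality_rate_per_day,0.0037999,0.0006,0.002,0.005
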