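quantity,value
total_token_types,48848
singleton_token_types,20293
informative_token_types_min,192
informative_token_types_max,592
chronic_pain_f1_wcnn_balanced_pct,55.96
chronic_pain_f1_wscnn_case_sensitive_pct,61.78
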