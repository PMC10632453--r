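{"beta_cp":0.812,"beta_age":0.00638,"intercept":-0.191,"residual_sd":null,"r_squared":0.53,"n_fit":null,"baseline_month":0,"horizon_month":12,"provenance":"published"}
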