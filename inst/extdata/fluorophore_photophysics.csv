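name,lambda_abs_nm,lambda_ems_nm,tau_fl_ns,epsilon,phi,tau_dsc_us,tau_gsr_ms
mCherry,587,610,1.72,74000,0.25,60,1.0
mCherry-d,572,608,2.22,55000,0.27,5.8,0.5
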