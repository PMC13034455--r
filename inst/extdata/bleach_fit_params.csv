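sample,intensity_kw_cm2,a1_pct,tau1_ms,a2_pct,tau2_ms,tau_avg_ms
mCherry,1,67,10,33,87,35
mCherry,5,66,10,34,67,29
mCherry,10,60,10,40,43,23
mCherry-d,1,22,63,78,12,23
mCherry-d,5,10,63,90,5,11
mCherry-d,10,9,63,91,4,9
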