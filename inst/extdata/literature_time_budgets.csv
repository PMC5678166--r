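population,raiding,foraging_pct
published_range_low,non-raiding,20.3
published_range_high,non-raiding,59.3
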