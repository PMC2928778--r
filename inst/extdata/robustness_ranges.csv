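parameter,low,high,context,provenance
death_threshold_pct,7.5,17.5,completely hollow luminal space preserved,death-threshold robustness of the tuned baseline
growth_threshold_pct_at_E12.5,15,20,acini stay comparable to experiment,growth-threshold robustness at ECM threshold 12.5
growth_threshold_pct_at_E15,22.5,25,acini stay comparable to experiment,growth-threshold robustness at ECM threshold 15
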