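line,mean_h,sd_h,provenance
MCF10A,47.7,9.4,effective doubling time of the tuned baseline simulation
HER2-YVMA,33.3,6.8,effective doubling time of the tuned mutant simulation
MCF10A_population_literature,48,NA,reported MCF10A population doubling time
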