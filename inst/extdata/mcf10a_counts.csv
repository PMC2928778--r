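day,area_mean_um2,area_sd_um2,count_mean,count_sd,provenance
4,3490,810,11.5,2,MCF10A 3D culture central cross-sections
8,7640,1550,25.8,6.3,MCF10A 3D culture central cross-sections
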