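day,area_mean_um2,area_sd_um2,count_mean,count_sd,provenance
4,6180,1280,20.2,4.2,MCF10A-HER2-YVMA 3D culture central cross-sections
8,11450,2770,40.7,10.7,MCF10A-HER2-YVMA 3D culture central cross-sections
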