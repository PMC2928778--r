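label,G,D,E,lumen_sensing,contact_inhibition_released,provenance
mutant_i,0,40,12.5,FALSE,FALSE,non-polarized mutant with no cell growth
mutant_ii,5,45,12.5,FALSE,FALSE,non-stabilized mutant growing on the outer rim
mutant_iii,0,65,12.5,FALSE,FALSE,disorganized mutant growing throughout (HER2-YVMA-like)
mutant_iv,10,5,12.5,TRUE,FALSE,non-stabilized mutant with luminal growth promotion
mutant_v,0,5,12.5,FALSE,FALSE,non-polarized hollow mutant with growing rim
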