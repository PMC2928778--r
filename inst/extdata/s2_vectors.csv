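label,G,D,E,provenance
acinus_i,25,10,14.5,threshold vector of hollow acinus i (matches experiment)
acinus_ii,15,12.5,12,threshold vector of hollow acinus ii (matches experiment)
acinus_iii,15,12.5,14.5,threshold vector of hollow acinus iii (too large)
acinus_iv,20,17.5,9.5,threshold vector of hollow acinus iv (too small)
acinus_v,15,17.5,7,threshold vector of hollow acinus v (too small)
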