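region,pearson_r,r_squared_printed,slope,intercept,p_label
ACC,0.8429,0.710,0.016,-0.858,<0.01
PL,0.8192,0.671,0.026,-0.767,<0.01
IL,NA,0.008,0.007,0.359,0.803
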