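analyte,medium,slope,intercept,r_squared
metalaxyl-M,solvent,175194,4646.8,0.9919
metalaxyl-M,matrix,71002,149.65,0.9996
azoxystrobin,solvent,505999,9186.5,0.9946
azoxystrobin,matrix,237639,1759.7,0.9983
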