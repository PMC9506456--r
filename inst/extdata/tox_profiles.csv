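compound,noael,is_index,uf_interspecies,uf_intraspecies
metalaxyl-M,8,FALSE,10,10
azoxystrobin,18.2,TRUE,10,10
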