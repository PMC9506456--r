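jurisdiction,commodity,analyte,mrl
China,scallion,azoxystrobin,7
EU,Welsh onion,azoxystrobin,10
US,"Onion, green, subgroup 3-07B",azoxystrobin,7.5
EU,Welsh onion,metalaxyl-M,0.3
US,"Onion, green, subgroup 3-07B",metalaxyl-M,10
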