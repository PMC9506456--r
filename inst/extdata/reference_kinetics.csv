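analyte,site,half_life_days
metalaxyl-M,Shandong,1.15
metalaxyl-M,Guizhou,1.06
azoxystrobin,Shandong,2.28
azoxystrobin,Guizhou,3.89
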