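analyte,site,interval_days,concentration,loq
metalaxyl-M,Beijing,7,0.003,0.001
metalaxyl-M,Beijing,7,0.003,0.001
metalaxyl-M,Beijing,10,0.005,0.001
metalaxyl-M,Beijing,10,0.004,0.001
metalaxyl-M,Shandong,7,0.002,0.001
metalaxyl-M,Shandong,7,0.002,0.001
metalaxyl-M,Shandong,10,0.003,0.001
metalaxyl-M,Shandong,10,0.002,0.001
metalaxyl-M,Guizhou,7,<0.001,0.001
metalaxyl-M,Guizhou,7,<0.001,0.001
metalaxyl-M,Guizhou,10,<0.001,0.001
metalaxyl-M,Guizhou,10,<0.001,0.001
metalaxyl-M,Hunan,7,0.082,0.001
metalaxyl-M,Hunan,7,0.088,0.001
metalaxyl-M,Hunan,10,0.049,0.001
metalaxyl-M,Hunan,10,0.049,0.001
azoxystrobin,Beijing,7,0.363,0.001
azoxystrobin,Beijing,7,0.190,0.001
azoxystrobin,Beijing,10,0.377,0.001
azoxystrobin,Beijing,10,0.492,0.001
azoxystrobin,Shandong,7,1.420,0.001
azoxystrobin,Shandong,7,1.360,0.001
azoxystrobin,Shandong,10,0.071,0.001
azoxystrobin,Shandong,10,0.043,0.001
azoxystrobin,Guizhou,7,0.314,0.001
azoxystrobin,Guizhou,7,0.326,0.001
azoxystrobin,Guizhou,10,0.350,0.001
azoxystrobin,Guizhou,10,0.334,0.001
azoxystrobin,Hunan,7,4.687,0.001
azoxystrobin,Hunan,7,4.687,0.001
azoxystrobin,Hunan,10,4.368,0.001
azoxystrobin,Hunan,10,4.203,0.001
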