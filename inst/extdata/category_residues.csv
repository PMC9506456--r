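category,compound,crop,stmr,hr,c_index_reported
Rice and products,metalaxyl-M,,,,0.160
Rice and products,azoxystrobin,Rice,0.160,0.230,0.160
Flour and products,metalaxyl-M,,,,0.023
Flour and products,azoxystrobin,Wheat,0.023,0.180,0.023
Other cereals,metalaxyl-M,Corn,0.020,0.020,0.051
Other cereals,azoxystrobin,Corn,0.005,0.005,0.051
Potatoes and products,metalaxyl-M,Potato,0.011,0.039,0.045
Potatoes and products,azoxystrobin,Potato,0.020,0.020,0.045
Legumes and products,metalaxyl-M,Soybean,0.020,0.020,0.246
Legumes and products,azoxystrobin,Soybean,0.200,0.265,0.246
Dark vegetables,metalaxyl-M,Tomato,0.034,0.051,0.996
Dark vegetables,azoxystrobin,Water spinach,0.920,4.000,0.996
Light vegetables,metalaxyl-M,Cauliflower,0.109,0.454,0.488
Light vegetables,azoxystrobin,Loofah,0.240,0.540,0.488
Fruits,metalaxyl-M,Watermelon,0.010,0.010,0.723
Fruits,azoxystrobin,Grape,0.700,3.220,0.723
Vegetable oil,metalaxyl-M,,,,0.050
Vegetable oil,azoxystrobin,Peanut,0.050,0.160,0.050
Soy sauce,metalaxyl-M,Scallion,0.0025,0.088,0.867
Soy sauce,azoxystrobin,Scallion,0.861,4.687,0.867
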