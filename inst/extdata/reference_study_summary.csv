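# scenario_class,participant,offences_per_s,mean_angular_speed,sd_angular_speed
urban,7,0.142,1.731,27.048
urban,14,0.109,1.880,11.016
urban,1,0.092,1.921,31.524
urban,2,0.085,2.080,47.617
urban,3,0.071,2.038,28.986
urban,10,0.063,1.760,14.505
urban,4,0.062,2.036,23.957
urban,8,0.055,1.724,12.906
urban,13,0.046,1.952,12.706
urban,5,0.045,1.945,34.903
urban,12,0.032,1.622,17.254
urban,15,0.030,1.798,17.292
urban,11,0.029,1.644,13.892
urban,6,0.027,1.940,30.543
urban,9,0.026,1.640,20.727
interurban,2,0.1023,2.085,28.251
interurban,4,0.0727,2.043,17.206
interurban,3,0.0683,2.000,20.252
interurban,6,0.0629,1.981,15.927
interurban,1,0.0570,1.966,27.092
interurban,12,0.0508,1.935,15.324
interurban,13,0.0464,2.701,10.413
interurban,9,0.0438,1.961,16.108
interurban,11,0.0428,1.952,10.051
interurban,7,0.0388,2.100,17.414
interurban,10,0.0360,2.354,14.759
interurban,15,0.0355,1.997,16.607
interurban,14,0.0326,2.157,7.986
interurban,8,0.0247,1.789,11.534
interurban,5,0.0079,1.986,21.355
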