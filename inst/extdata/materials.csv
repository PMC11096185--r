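name,density,radiation_length_cm,stopping_power_MeV_cm
vacuum,0,Inf,0
water,1.0,36.08,2.0
air,0.0012,30390,0.0025
pmma,1.19,34.07,2.3
kapton,1.42,28.6,2.7
mylar,1.40,28.5,2.7
steel,8.0,1.76,11.6
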