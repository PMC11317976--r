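id,charge,dG_cont,dW,dE,f_d_printed,dG_ccsa_printed
BH1,1,-60.09,-14.35,-34.53,1.00,-73.44
BH2,1,-74.00,-6.24,-29.84,1.00,-79.24
BH3,1,-66.95,-5.64,-25.86,1.00,-71.57
BH4,1,-63.15,-6.31,-24.97,1.00,-68.45
BH5,1,-58.95,-5.55,-22.07,1.00,-63.48
BH6,1,-59.55,-6.24,-22.80,1.00,-64.78
BH7,1,-61.06,-4.42,-22.54,0.97,-64.39
BH8,1,-56.13,-5.82,-21.24,1.00,-60.94
BH9,1,-61.11,-7.40,-24.84,1.00,-67.51
BH10,1,-51.59,-1.63,-15.24,0.36,-51.82
BH11,1,-56.82,-6.24,-22.54,1.00,-62.05
BH12,1,-54.15,-6.88,-22.70,1.00,-60.03
BH13,1,-72.05,-6.62,-28.36,1.00,-77.67
BH14,1,-67.98,-16.33,-40.12,1.00,-83.31
BH15,1,-54.73,-13.42,-29.13,1.00,-67.14
BH16,1,-58.57,-13.13,-31.10,1.00,-70.71
BH17,1,-50.43,-9.56,-23.41,1.00,-59.00
BH18,1,-60.87,-20.66,-38.20,1.00,-80.53
BH19,1,-62.19,-13.14,-32.22,1.00,-74.33
BH20,1,-52.82,-12.72,-26.96,1.00,-64.54
BH21,1,-53.04,-10.80,-18.82,1.00,-62.83
BH22,1,-61.30,-6.76,-24.02,1.00,-67.05
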