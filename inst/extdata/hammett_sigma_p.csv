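substituent,sigma_p
H,0.00
p-OH,-0.37
p-NO2,0.78
p-OCH3,-0.27
p-F,0.06
p-Cl,0.23
p-Br,0.23
p-C2H5,-0.15
p-SO2CH3,0.72
p-NH2,-0.66
p-CH3,-0.17
p-CN,0.66
p-COCH3,0.50
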