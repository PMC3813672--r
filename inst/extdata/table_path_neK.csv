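variable,direct_cc,indirect_cc,path_cc
s,-0.86,0.19,-0.25
na_k,-0.66,0.02,0.03
tn,-0.64,0.03,-0.03
na,-0.61,-0.34,-0.37
pha,-0.46,0.03,0.16
orp,-0.41,0.1,-0.42
mg,0.04,-0.67,-0.34
co3,0.1,1.18,0.56
k,0.44,-0.14,0.2
ph,0.46,-0.16,-0.5
hmi,0.48,0.07,0.06
cia,0.56,0.05,-0.07
wsk,0.77,0.01,0.01
som,0.8,-0.11,-0.14
ek,0.98,0.76,0.69
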