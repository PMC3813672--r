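variable,direct_cc,indirect_cc,path_cc
s,-0.83,-0.28,0.36
na_k,-0.67,-0.03,-0.04
tn,-0.62,-0.04,0.04
na,-0.55,0.46,0.54
pha,-0.51,-0.06,-0.24
orp,-0.38,-0.16,0.6
mg,0.07,0.95,0.49
co3,0.11,-1.7,-0.81
ph,0.47,0.23,0.71
k,0.48,0.21,-0.3
cia,0.51,-0.07,0.1
hmi,0.54,-0.09,-0.09
wsk,0.73,-0.01,-0.02
som,0.74,0.18,0.2
nek,0.98,1.49,1.44
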