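variable,direct_cc,indirect_cc,path_cc
pha,-0.65,-0.32,-0.38
s,-0.56,0.17,-0.8
na,-0.55,-1.15,-0.78
na_k,-0.52,-0.01,-0.01
tn,-0.41,0.23,-0.38
orp,-0.22,0.02,-1.28
mg,-0.14,-0.79,-0.37
co3,-0.07,-0.53,-0.24
ph,0.14,-0.35,-1.87
hmi,0.39,0.2,0.29
k,0.41,0.02,-0.01
cia,0.47,2.02,-1.61
som,0.58,0.06,0.25
ek,0.73,0.05,0.14
nek,0.77,NA,NA
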