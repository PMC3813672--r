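var1,var2,r,flag
cia,som,0.61,a
na_k,som,-0.52,a
na_k,cia,0.829,b
tn,som,-0.61,a
wsk,som,0.58,a
wsk,na_k,-0.52,a
nek,som,0.8,b
nek,cia,0.56,a
nek,na_k,-0.66,b
nek,tn,-0.64,b
nek,wsk,0.77,b
ek,som,0.74,b
ek,cia,0.51,a
ek,na_k,-0.67,b
ek,tn,-0.62,a
ek,wsk,0.73,b
ek,nek,0.98,b
bacteria,som,0.55,a
bacteria,nek,0.53,a
orp,som,-0.59,a
orp,tc,-0.56,a
orp,tn,0.66,b
ph,som,0.58,a
ph,tc,0.66,b
ph,tn,-0.68,b
ph,orp,-0.95,b
nha,ph,-0.57,a
pha,cia,-0.51,a
pha,na_k,0.64,
pha,wsk,-0.65,b
pha,ek,-0.51,a
hmi,ek,0.54,a
hmc,hmi,0.93,b
co3,cia,-0.62,b
co3,na_k,0.56,
co3,orp,-0.5,a
k,cia,0.53,a
k,na_k,-0.79,b
k,pha,-0.77,b
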