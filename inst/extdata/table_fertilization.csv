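component,opt,sw,sk,swk
urea,6.65,6.65,6.65,6.65
na2po4_2h2o,11.72,11.72,11.72,11.72
kcl,6.83,6.83,0,0
caco3,2.13,2.13,2.13,2.13
h3bo3,1,1,1,1
znso4_7h2o,1.87,1.87,1.87,1.87
mgso4_7h2o,2.61,2.61,2.61,2.61
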