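group,tc,tn,som,pha,nha,hmi,hmc
NR1-16,0.00451,0.00171,7.88,4.53,2.59,1.47,0.92
R17-32,0.00441,0.00574,5.67,4.84,3.52,0.33,0.33
NR33-48,0.00534,0.00202,7.32,3.48,3.67,0.42,0.37
R49-64,0.00374,0.0104,5.54,4.11,2.55,0.45,0.32
N65-80,0.0045,0.00164,8.01,5.33,3.89,1.35,1.24
R81-96,0.00364,0.00424,5.79,5.26,4.58,0.42,0.23
NR97-112,0.00301,0.00393,8.53,3.62,3.28,0.66,0.41
R113-128,0.0028,0.0131,5.7,4.41,3.68,0.46,0.27
NR129-144,0.00352,0.00346,8.3,4.46,3.7,0.35,0.28
R145-160,0.00322,0.0202,5.38,5,3.82,0.3,0.3
NR161-176,0.00318,0.00397,7.84,4.9,1.75,0.88,0.45
R177-192,0.00312,0.0231,6.79,6.89,3.95,0.34,0.26
NR193-208,0.00357,0.00324,8.45,4.57,3.82,0.25,0.19
R209-224,0.00379,0.0267,5.79,5.43,4.22,0.44,0.36
NR225-240,0.0043,0.00383,8.01,4.94,4.61,0.52,0.32
R241-256,0.00437,0.0275,6.23,4.7,4.08,0.36,0.18
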