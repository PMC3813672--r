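group,na,mg_a,al,si,fe,mg_b,ca,p,co3,s,cl,k,wsk,nek,ek,wsk_w,nek_w,ek_w,bact_seedling,bact_budding,bact_wadding,tc,tn,som,pha,nha,hmi,hmc,orp,ph,ba,na_k,ica,saf,cia
NR1-16,0.44,0.39,6.49,36.86,3.35,1.49,0.37,491.01,49.74,219.34,119.8,14.93,27.1,134.9,58.64,67.57,174.48,62.9,0.8,2.1,1.6,0.00451,0.00171,7.88,4.53,2.59,1.47,0.92,17.3,7.27,0.45,0.29,1.03,8.73,76.08
R17-32,0.45,0.37,6.53,37.16,3.34,1.49,0.39,507.57,49.38,243.65,228.2,14.9,12.03,54.21,14.32,59.36,155.15,66.59,1.5,5.2,1.4,0.00441,0.00574,5.67,4.84,3.52,0.33,0.33,18.65,6.84,0.44,0.3,1.03,8.77,75.82
NR33-48,0.44,0.39,6.5,36.92,3.33,1.49,0.38,494.36,49.72,218.56,122.07,14.9,20.01,134.13,50.84,76.97,177.27,55.87,0.7,4.3,1.7,0.00534,0.00202,7.32,3.48,3.67,0.42,0.37,13.8,7.2,0.45,0.29,1.03,8.75,76.02
R49-64,0.44,0.39,6.51,36.94,3.34,1.49,0.39,483.04,49.64,251.93,217.78,14.87,9.22,58.27,12.21,123.72,170.67,71.24,1.1,3.4,1.9,0.00374,0.0104,5.54,4.11,2.55,0.45,0.32,30.24,6.5,0.45,0.3,1.04,8.74,75.95
N65-80,0.44,0.39,6.46,36.93,3.32,1.47,0.36,488.97,49.77,220.97,68.15,14.7,24.8,121.55,40.27,53.02,190.22,59.93,0.9,17,14,0.0045,0.00164,8.01,5.33,3.89,1.35,1.24,22.66,6.79,0.45,0.3,1.03,8.8,76.18
R81-96,0.47,0.42,6.3,36.38,3.29,1.46,0.4,515.89,50.45,248.77,80.32,14.57,5.65,39.17,6.28,61.31,153.27,57.35,1,87,30,0.00364,0.00424,5.79,5.26,4.58,0.42,0.23,22.68,6.73,0.48,0.32,1.08,8.86,75.08
NR97-112,0.44,0.38,6.49,37.04,3.35,1.48,0.37,506.34,49.62,218.38,82.48,14.75,41.28,101.36,27.46,56.24,167.15,69.44,1.2,26,19,0.00301,0.00393,8.53,3.62,3.28,0.66,0.41,10.22,6.94,0.44,0.3,1.03,8.78,76.21
R113-128,0.44,0.38,6.53,37.09,3.35,1.48,0.4,518.35,49.48,243.94,89.5,14.8,6.05,42.83,5.23,58.41,149.91,52.24,1.9,39,24,0.0028,0.0131,5.7,4.41,3.68,0.46,0.27,65.8,6.09,0.45,0.3,1.03,8.74,76
NR129-144,0.44,0.39,6.38,36.84,3.29,1.48,0.36,481.3,49.95,224.13,152.4,14.77,38.55,158.29,56.41,68.09,190.55,65.03,0.1,1.2,0.5,0.00352,0.00346,8.3,4.46,3.7,0.35,0.28,18.5,6.93,0.45,0.3,1.04,8.88,75.88
R145-160,0.45,0.39,6.39,36.94,3.27,1.47,0.38,512.73,49.84,237.7,201.2,14.73,15.92,78.62,23.18,60.89,167.13,52.79,0.4,1.3,0.7,0.00322,0.0202,5.38,5,3.82,0.3,0.3,80.84,5.79,0.46,0.31,1.04,8.9,75.67
NR161-176,0.43,0.38,6.49,37.09,3.32,1.49,0.37,484.59,49.58,225.39,142.88,14.87,88.78,162.24,61.11,70.46,181.02,55.25,0.9,4.3,2.2,0.00318,0.00397,7.84,4.9,1.75,0.88,0.45,31.46,6.48,0.44,0.29,1.02,8.8,76.16
R177-192,0.45,0.38,6.51,37.01,3.33,1.48,0.39,496.2,49.57,236.79,189.7,14.83,18.61,70.07,19.27,64.82,185.07,59.89,0.3,1.7,0.6,0.00312,0.0231,6.79,6.89,3.95,0.34,0.26,62.82,5.85,0.45,0.3,1.03,8.75,75.92
NR193-208,0.44,0.39,6.43,36.92,3.31,1.47,0.36,502.75,49.83,223.08,71.6,14.73,13.26,99.74,30.21,63.65,171.35,62.95,0.8,1.9,1.6,0.00357,0.00324,8.45,4.57,3.82,0.25,0.19,19.33,6.87,0.45,0.3,1.03,8.83,76.06
R209-224,0.45,0.38,6.43,37.08,3.32,1.46,0.39,491.22,49.64,245.74,81.48,14.63,6.41,38.74,7.63,61.96,162.21,52.09,0.7,7.1,4,0.00379,0.0267,5.79,5.43,4.22,0.44,0.36,52.48,6.19,0.45,0.31,1.04,8.86,75.76
NR225-240,0.44,0.38,6.46,37,3.31,1.47,0.38,509.11,49.7,228.9,90.5,14.73,25.27,105.8,29.54,64.59,182.24,59.77,0.1,2.3,0.9,0.0043,0.00383,8.01,4.94,4.61,0.52,0.32,13.72,6.98,0.45,0.3,1.03,8.83,75.99
R241-256,0.44,0.37,6.46,37.28,3.34,1.47,0.39,498.72,49.4,239.9,87.4,14.73,6.56,44.8,5.31,72.96,154.08,60.7,1.2,6.3,2.8,0.00437,0.0275,6.23,4.7,4.08,0.36,0.18,20.54,6.86,0.45,0.3,1.04,8.87,75.84
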