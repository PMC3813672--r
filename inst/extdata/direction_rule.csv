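target,v1,v2,z,dir1,dir2
nek,-0.89,-1.16,-1.06,beta,chi
nek,-0.78,-1.04,-1.2,alpha,chi
nek,-0.02,-0.44,-0.47,alpha,chi
nek,-0.35,-0.25,-0.27,alpha,chi
nek,-1.25,-1.16,-1.11,beta,chi
nek,-0.55,-1.11,-1.19,beta,gamma
nek,-1.93,-0.81,-0.75,beta,chi
nek,-0.91,-0.7,-0.84,beta,gamma
nek,1.05,0.08,0.36,beta,chi
nek,-0.56,0.11,0.22,alpha,chi
nek,3.78,1.69,1.68,beta,chi
nek,1.37,1.45,1.58,alpha,chi
nek,1.24,-0.03,0.26,beta,chi
nek,0.42,0.63,0.73,beta,chi
nek,-0.15,1.17,1.02,beta,gamma
nek,-0.47,1.56,1.04,beta,gamma
ek,-0.78,-1.39,-1.14,theta,omega
ek,-0.78,-1.51,-1.02,theta,lambda
ek,-0.19,-0.5,-0.44,theta,lambda
ek,-0.32,-0.28,-0.24,theta,lambda
ek,-0.8,-1.79,-1.14,theta,omega
ek,-0.82,-1.19,-1.09,theta,lambda
ek,-0.65,-2.11,-0.79,theta,omega
ek,-0.51,-1.48,-0.69,theta,lambda
ek,0.14,1.43,0.08,epsilon,lambda
ek,-0.45,0.54,0.11,theta,omega
ek,3.24,1.28,1.66,epsilon,lambda
ek,0.79,2.73,1.42,theta,lambda
ek,0.92,0.17,-0.03,epsilon,lambda
ek,0.11,1.45,0.61,theta,omega
ek,-0.12,1.76,1.14,theta,omega
ek,0.23,0.9,1.53,theta,omega
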