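name,dili_label,c1,c2,c3,c4,c5,c6,c7,cmax_um,mechanisms
amiodarone,DILI,3,5,10,30,50,100,300,0.807,bd
bosentan,DILI,3,5,10,30,50,100,300,7.4,c
buspirone,non-DILI,3,5,10,30,50,100,300,0.005,
diclofenac,DILI,10,30,50,100,300,500,1000,7.44,abc
entacapone,non-DILI,10,30,50,100,300,500,1000,1.5,
metformin,non-DILI,30,50,100,300,500,1000,3000,7.74,
nefazodone,DILI,3,5,10,30,50,100,300,0.859,ac
paracetamol,DILI,30,100,300,1000,3000,10000,30000,139,a
perhexiline,DILI,3,5,10,30,50,100,300,1.525,cd
pioglitazone,non-DILI,3,5,10,30,50,100,300,2.672,
tolcapone,DILI,10,30,50,100,300,500,1000,27.81,ac
troglitazone,DILI,3,5,10,30,50,100,300,6.387,abcd
ximelagatran,DILI,3,5,10,30,50,100,300,0.3,e
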