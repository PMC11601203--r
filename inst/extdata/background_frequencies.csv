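residue,probability
A,0.0826330532212885
C,0.0138055222088836
D,0.0546218487394958
E,0.0672268907563025
F,0.0387154861944778
G,0.070828331332533
H,0.0227090836334534
I,0.0591236494597839
K,0.0580232092837135
L,0.0965386154461785
M,0.024109643857543
N,0.0406162464985994
P,0.0474189675870348
Q,0.0393157262905162
R,0.0553221288515406
S,0.0665266106442577
T,0.0536214485794318
V,0.0686274509803921
W,0.0110044017607043
Y,0.0292116846738695
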