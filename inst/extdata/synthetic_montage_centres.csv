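name,inclination_deg,azimuth_deg
Fp1,72,-18
Fp2,72,18
AF3,60,-25
AF4,60,25
F7,72,-54
F3,48,-35
Fz,36,0
F4,48,35
F8,72,54
FC5,60,-62
FC1,25,-35
FCz,18,0
FC2,25,35
FC6,60,62
T7,72,-90
C3,36,-90
Cz,0,0
C4,36,90
T8,72,90
CP5,60,-118
CP1,25,-145
CP2,25,145
CP6,60,118
P7,72,-126
P3,48,-145
Pz,36,180
P4,48,145
P8,72,126
POz,54,180
O1,72,-162
Oz,72,180
O2,72,162
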