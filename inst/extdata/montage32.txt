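# Reduced 32-channel montage: the international 10-20 positions present in
# the 116-channel study montage, padded with common 10-10 positions to
# reach 32. Editable stand-in; one label per line.
FP1
FP2
F7
F3
Fz
F4
T7
C3
Cz
C4
T8
P7
P3
Pz
P4
P8
O1
O2
FC1
FC2
FC5
FC6
CP1
CP2
CP5
CP6
PO3
PO4
PO7
PO8
AF3
AF7
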