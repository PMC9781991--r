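class,sensitivity,specificity,accuracy,efficiency
FB,93.40,97.47,96.66,95.84
EB,90.47,98.43,96.84,95.24
FD,85.18,94.15,92.35,90.56
ED,73.83,95.31,91.02,86.72
RR,82.13,95.86,93.10,90.36
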