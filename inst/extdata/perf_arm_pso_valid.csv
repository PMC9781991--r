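class,sensitivity,specificity,accuracy,efficiency
FB,79.83,92.38,89.88,87.36
EB,78.36,89.42,87.21,84.99
FD,69.70,94.77,89.75,84.74
ED,69.57,95.49,90.30,85.12
RR,86.10,98.81,96.27,93.73
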