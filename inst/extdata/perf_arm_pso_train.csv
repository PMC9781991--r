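class,sensitivity,specificity,accuracy,efficiency
FB,79.88,92.56,90.01,87.48
EB,78.742,89.328,87.22,85.097
FD,68.15,94.82,89.5,84.16
ED,69.72,95.31,90.20,85.08
RR,85.99,98.60,96.08,93.562
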