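class,sensitivity,specificity,accuracy,efficiency
FB,93.20,97.19,96.38,95.59
EB,89.57,98.39,96.61,94.86
FD,84.47,94.03,92.14,90.22
ED,72.940,95.32,90.81,86.36
RR,81.75,95.59,92.88,90.07
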