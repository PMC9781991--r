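class,sensitivity,specificity,accuracy,efficiency
AP,92.62,98.40,97.56,96.19
AT,89.12,98.09,96.84,94.68
LP,94.48,98.63,98.03,97.052
LT,88.03,98.58,97.02,94.54
PD,83.74,97.83,95.85,92.47
PI,83.98,97.77,95.81,92.52
RR,95.38,98.61,98.15,97.38
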