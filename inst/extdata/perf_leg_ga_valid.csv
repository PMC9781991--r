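class,sensitivity,specificity,accuracy,efficiency
AP,92.99,98.4,97.67,96.37
AT,89.53,98.16,96.91,94.87
LP,94.71,98.49,97.95,97.05
LT,88.40,98.677,97.23,94.77
PD,83.84,97.86,95.84,92.51
PI,83.94,97.92,95.91,92.59
RR,96.59,98.75,98.44,97.93
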