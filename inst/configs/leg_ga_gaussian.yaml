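# Right-leg style experiment: 8 subjects x 7 movements x 20 reps at 1 kHz,
# ANOVA prescreen, then GA selection (pop 100, 2% mutation, 200 iterations)
# with a Gaussian-kernel SVM fitness. With the 1.97 s end trim the 6 s
# movement phase yields 64 windows of 250/190 ms per recording.
database:
  n_subjects: 8
  movements: [AP, AT, LP, LT, PD, PI, RR]
  n_reps: 20
  n_channels: 4
  fs: 1000
  duration: 7
  rest_lead: 1
  rest_label: RR
  seed: 101
filter: {enabled: true, low_hz: 10, high_hz: 500, order: 4}
window: {length_ms: 250, overlap_ms: 190}
trim: {start_s: 1.0, end_s: 1.97}
prescreen: {enabled: true, alpha: 0.05}
selector:
  method: ga
  pop_size: 100
  mutation_rate: 0.02
  max_iterations: 200
  seed: 11
svm: {kernel: gaussian, C: 1, standardize: true}
cv: {k: 10}
split: {select_frac: 0.7, train_frac: 0.7, seed: 21}
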