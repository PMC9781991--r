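# Right-arm style experiment: 8 subjects x 5 movements x 20 reps at 1.5 kHz,
# no prescreen (all 104 = 26 x 4 gene columns enter the GA), Gaussian SVM.
database:
  n_subjects: 8
  movements: [FB, EB, FD, ED, RR]
  n_reps: 20
  n_channels: 4
  fs: 1500
  duration: 8
  rest_lead: 2
  rest_label: RR
  seed: 102
filter: {enabled: true, low_hz: 10, high_hz: 500, order: 4}
window: {length_ms: 250, overlap_ms: 190}
trim: {start_s: 2.0, end_s: 0}
prescreen: {enabled: false}
selector:
  method: ga
  pop_size: 100
  mutation_rate: 0.02
  max_iterations: 100
  seed: 12
svm: {kernel: gaussian, C: 1, standardize: true}
cv: {k: 10}
split: {select_frac: 0.7, train_frac: 0.25, seed: 22}
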