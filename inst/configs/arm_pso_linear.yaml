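# Right-arm experiment with binary PSO selection (10 particles, w = 0.9,
# c1 = c2 = 2, 100 iterations) and a linear-kernel SVM fitness.
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
  method: pso
  n_particles: 10
  w: 0.9
  c1: 2
  c2: 2
  v_clamp: 6
  max_iterations: 100
  seed: 13
svm: {kernel: linear, C: 1, standardize: true}
cv: {k: 10}
split: {select_frac: 0.7, train_frac: 0.25, seed: 22}
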