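# a small synthetic cohort for quick experiments
n_males: 6
n_females: 6
fraction_unornamented_females: 0.33
temperatures:
  cold: 23
  warm: 33
n_replicates: 3
noise_sd: 0.3
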