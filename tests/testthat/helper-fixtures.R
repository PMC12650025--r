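# Shared fixtures, built in code at test time.

# Small zero-noise ground truth on the canonical 19-channel montage.
fix_gt <- function(noise_sd = 0) {
  control_ground_truth(19L, noise_sd = noise_sd)
}

# Short synthetic record with known labels.
fix_record <- function(seconds = 10, fs = 128, noise_sd = 0, seed = 7L,
                       gt = fix_gt(noise_sd)) {
  labels <- simulate_state_sequence(gt, round(seconds * fs), fs, seed = seed)
  synthesize_eeg(gt, labels, fs_hz = fs, seed = seed)
}

# Tiny network configuration for exact-arithmetic tests.
fix_net_cfg <- function(Tn = 8L, dropout = 0) {
  cnngru_config(input_steps = Tn, input_dim = 1L, conv_filters_1 = 3L,
                conv_filters_2 = 4L, pool_size = 2L, gru_units = 3L,
                dense_units = 5L, dropout_rate = dropout)
}

# Zeroed parameter set for a configuration.
fix_zero_params <- function(cfg) {
  p <- cnngru_init(cfg, seed = 1L)
  bn <- attr(p, "bn_state")
  p <- lapply(p, function(q) q * 0)
  attr(p, "bn_state") <- bn
  p
}
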