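# shared fixtures: random SPD matrices and small synthetic epoch sets

# well-conditioned random SPD matrix
rspd <- function(n, jitter = 0.5) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) / n + diag(n) * jitter
}

# random symmetric matrix
rsym <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  (A + t(A)) / 2
}

# seed some code without leaking the seed into later tests' expectations
with_seed_local <- function(seed, code) {
  set.seed(seed)
  code
}

# small, fast simulator configuration for pipeline-level tests
small_sim <- function(seed, trials_per_class = 8, n_channels = 6,
                      duration = 2, gain = 2, ...) {
  sim_config(trials_per_class = trials_per_class, n_channels = n_channels,
             duration = duration, class_gain = gain, seed = seed, ...)
}

# matching pipeline configuration: fixed G, small C grid, few folds
small_cfg <- function(G = 6, seed = 1, n_folds = 4, ...) {
  mi_config(G = G, C_grid = c(0.1, 1, 10), n_folds = n_folds,
            time_windows = time_window(0.2, 1.8), seed = seed, ...)
}
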