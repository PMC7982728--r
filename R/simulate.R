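#' Configuration for the motor-imagery EEG simulator
#'
#' Describes a session of multiclass motor-imagery-like EEG: spatially mixed
#' 1/f background activity plus, for each class, band-limited oscillatory
#' sources projected through class-specific spatial patterns (an ERD/ERS-like
#' covariance difference), plus white sensor noise. Defaults emulate a
#' 22-channel, 4-class, 250 Hz recording with 40 trials per class and one
#' planted rhythm per class in the mu/beta range.
#'
#' @param n_classes number of motor-imagery classes.
#' @param trials_per_class trials per class (balanced).
#' @param n_channels number of EEG channels.
#' @param fs sampling rate, Hz.
#' @param duration trial length, seconds.
#' @param t0 time of first sample relative to the cue, seconds.
#' @param class_bands tibble (`f_lo`, `f_hi`) or list of `c(lo, hi)`, one
#'   planted band per class.
#' @param class_gain amplitude gain of each class's band-limited sources
#'   relative to the background (recycled to `n_classes`).
#' @param sources_per_class number of band-limited sources per class.
#' @param background_exponent spectral exponent of the 1/f background.
#' @param background_amplitude RMS scale of the background at the sensors.
#' @param n_background_sources number of mixed background sources.
#' @param sensor_noise_sd standard deviation of additive white sensor noise.
#' @param seed master seed; all structure (patterns, mixing) and noise derive
#'   from it.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_classes = 4L, trials_per_class = 40L, n_channels = 22L,
                       fs = 250, duration = 4, t0 = 0,
                       class_bands = list(c(8, 12), c(12, 16), c(20, 24), c(26, 30)),
                       class_gain = 2, sources_per_class = 2L,
                       background_exponent = 1, background_amplitude = 1,
                       n_background_sources = 8L, sensor_noise_sd = 0.25,
                       seed = 1L) {
  class_bands <- as_band_tbl(class_bands)
  if (nrow(class_bands) != n_classes)
    stop("need one planted band per class", call. = FALSE)
  if (any(class_bands$f_hi >= fs / 2))
    stop("planted band at or above the Nyquist frequency", call. = FALSE)
  class_gain <- rep_len(class_gain, n_classes)
  if (any(class_gain < 0)) stop("gains must be >= 0", call. = FALSE)
  stopifnot(n_classes >= 2, trials_per_class >= 1, n_channels >= 2,
            fs > 0, duration > 0, sensor_noise_sd >= 0)
  structure(list(
    n_classes = as.integer(n_classes),
    trials_per_class = as.integer(trials_per_class),
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    t0 = t0, class_bands = class_bands, class_gain = class_gain,
    sources_per_class = as.integer(sources_per_class),
    background_exponent = background_exponent,
    background_amplitude = background_amplitude,
    n_background_sources = as.integer(n_background_sources),
    sensor_noise_sd = sensor_noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

# 1/f^alpha noise via spectral shaping of white noise; returns ns samples
pink_noise <- function(ns, fs, exponent) {
  w <- stats::rnorm(ns)
  W <- stats::fft(w)
  f <- c(1, seq_len(ns - 1))            # avoid dividing DC by zero
  f <- pmin(f, ns - f + 1)              # two-sided frequency index
  shape <- 1 / (f^(exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / ns
  x / stats::sd(x)
}

# white noise band-limited by the package's own zero-phase Butterworth
bandlimited_noise <- function(ns, fs, band, order = 4L) {
  flt <- design_bandpass(band, fs, order)
  x <- matrix(stats::rnorm(ns), 1L, ns)
  y <- as.numeric(cpp_filtfilt_rows(flt$b, flt$a, x))
  y / stats::sd(y)
}

#' Simulate one session of motor-imagery-like EEG
#'
#' Every trial receives spatially mixed 1/f background and white sensor
#' noise; a trial of class `c` additionally receives `sources_per_class`
#' band-limited Gaussian sources in the class's planted band, projected
#' through fixed class-specific unit-norm spatial patterns and scaled by the
#' class gain. Class-discriminative structure therefore lives entirely in
#' the spatial covariance, which is what covariance-based decoding consumes.
#' Output is bit-reproducible from the master seed.
#'
#' @param cfg a [sim_config()].
#' @param session_seed optional sub-seed for the noise realizations; the
#'   spatial structure (patterns, mixing) always derives from `cfg$seed`, so
#'   two sessions share geometry but not noise.
#' @return An [epoch_set()] with balanced, interleaved class labels.
#' @export
simulate_mi_epochs <- function(cfg, session_seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ns <- round(cfg$fs * cfg$duration)
  nc <- cfg$n_channels
  # fixed spatial structure from the master seed
  set.seed(cfg$seed %% .Machine$integer.max)
  A_bg <- matrix(stats::rnorm(nc * cfg$n_background_sources), nc)
  A_bg <- A_bg / sqrt(cfg$n_background_sources)
  patterns <- lapply(seq_len(cfg$n_classes), function(k) {
    Pm <- matrix(stats::rnorm(nc * cfg$sources_per_class), nc)
    sweep(Pm, 2, sqrt(colSums(Pm^2)), "/")   # unit-norm columns
  })
  # noise realizations from the session sub-seed
  if (is.null(session_seed)) session_seed <- cfg$seed
  set.seed(session_seed %% .Machine$integer.max)
  n_trials <- cfg$n_classes * cfg$trials_per_class
  labels <- rep(seq_len(cfg$n_classes), times = cfg$trials_per_class)
  data <- array(0, dim = c(n_trials, nc, ns))
  for (i in seq_len(n_trials)) {
    k <- labels[i]
    bg <- t(vapply(seq_len(cfg$n_background_sources),
                   function(s) pink_noise(ns, cfg$fs, cfg$background_exponent),
                   numeric(ns)))
    X <- cfg$background_amplitude * (A_bg %*% bg)
    if (cfg$class_gain[k] > 0) {
      band <- cfg$class_bands[k, ]
      src <- t(vapply(seq_len(cfg$sources_per_class),
                      function(s) bandlimited_noise(ns, cfg$fs, band),
                      numeric(ns)))
      X <- X + cfg$class_gain[k] * (patterns[[k]] %*% src)
    }
    if (cfg$sensor_noise_sd > 0)
      X <- X + matrix(stats::rnorm(nc * ns, sd = cfg$sensor_noise_sd), nc, ns)
    data[i, , ] <- X
  }
  epoch_set(data, labels, cfg$fs, cfg$t0)
}

#' Default two-session synthetic benchmark
#'
#' Two independent draws (train/test "sessions") from the same
#' [sim_config()], sharing spatial structure but with distinct noise
#' sub-seeds — a stand-in for session-to-session transfer evaluation.
#'
#' @param seed master seed.
#' @param cfg optional [sim_config()]; its `seed` is overridden by `seed`.
#' @return A list with elements `train` and `test`, both [epoch_set()]s.
#' @export
default_benchmark <- function(seed = 1L, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  else cfg$seed <- as.integer(seed)
  list(train = simulate_mi_epochs(cfg, session_seed = cfg$seed * 2654435L + 1L),
       test  = simulate_mi_epochs(cfg, session_seed = cfg$seed * 2654435L + 2L))
}
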