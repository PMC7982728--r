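#' Frequency band window
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return A one-row tibble with columns `f_lo`, `f_hi`.
#' @export
band_window <- function(f_lo, f_hi) {
  if (!(f_lo > 0 && f_hi > f_lo))
    stop("need 0 < f_lo < f_hi (got ", f_lo, ", ", f_hi, ")", call. = FALSE)
  tibble::tibble(f_lo = as.numeric(f_lo), f_hi = as.numeric(f_hi))
}

#' Time window relative to the cue
#'
#' @param t_start,t_end window bounds in seconds, `t_start < t_end`.
#' @return A one-row tibble with columns `t_start`, `t_end`.
#' @export
time_window <- function(t_start, t_end) {
  if (!(t_end > t_start))
    stop("need t_start < t_end", call. = FALSE)
  tibble::tibble(t_start = as.numeric(t_start), t_end = as.numeric(t_end))
}

as_band_tbl <- function(bands) {
  if (is.data.frame(bands)) {
    stopifnot(all(c("f_lo", "f_hi") %in% names(bands)))
    return(tibble::as_tibble(bands[c("f_lo", "f_hi")]))
  }
  # list of c(lo, hi) pairs
  dplyr::bind_rows(lapply(bands, function(b) band_window(b[[1]], b[[2]])))
}

as_window_tbl <- function(windows) {
  if (is.data.frame(windows)) {
    stopifnot(all(c("t_start", "t_end") %in% names(windows)))
    return(tibble::as_tibble(windows[c("t_start", "t_end")]))
  }
  dplyr::bind_rows(lapply(windows, function(w) time_window(w[[1]], w[[2]])))
}

#' Filter-bank specification
#'
#' An ordered list of band-pass windows plus the filter design used to
#' realize them (Butterworth, applied forward-backward for zero phase).
#'
#' @param bands tibble with columns `f_lo`, `f_hi` (one row per band) or a
#'   list of `c(lo, hi)` pairs, in Hz.
#' @param order Butterworth prototype order (default 4).
#' @param zero_phase apply the filter forward-backward?
#' @return An object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(bands, order = 4L, zero_phase = TRUE) {
  bands <- as_band_tbl(bands)
  if (nrow(bands) == 0L) stop("filter bank must contain at least one band",
                              call. = FALSE)
  if (any(bands$f_lo >= bands$f_hi) || any(bands$f_lo <= 0))
    stop("every band needs 0 < f_lo < f_hi", call. = FALSE)
  structure(list(bands = bands, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_bank_spec")
}

#' @export
print.filter_bank_spec <- function(x, ...) {
  cat(sprintf("<filter_bank_spec> %d band(s), Butterworth order %d%s\n",
              nrow(x$bands), x$order, if (x$zero_phase) ", zero-phase" else ""))
  print(x$bands, n = 6)
  invisible(x)
}

#' Design a band-pass filter
#'
#' Butterworth band-pass coefficients for one band at a given sampling rate.
#' If the nominal order is unstable for a very narrow band, the order is
#' lowered until the poles are inside the unit circle (a message is emitted).
#'
#' @param band one-row tibble (`f_lo`, `f_hi`) or numeric `c(lo, hi)`, Hz.
#' @param fs sampling rate, Hz.
#' @param order Butterworth prototype order.
#' @return List with components `b`, `a` (transfer-function coefficients)
#'   and `order` actually used.
#' @export
design_bandpass <- function(band, fs, order = 4L) {
  if (is.data.frame(band)) band <- c(band$f_lo[1L], band$f_hi[1L])
  lo <- band[[1L]]; hi <- band[[2L]]
  if (!(lo > 0 && hi > lo))
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (hi >= fs / 2)
    stop("band edge ", hi, " Hz is at or above the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  for (ord in seq(order, 1L)) {
    flt <- signal::butter(ord, c(lo, hi) / (fs / 2), type = "pass")
    roots <- polyroot(rev(flt$a))
    if (max(Mod(roots)) < 1 - 1e-8) {
      if (ord < order)
        message("narrow band (", lo, ", ", hi, ") Hz: Butterworth order reduced to ",
                ord, " for stability")
      return(list(b = as.numeric(flt$b), a = as.numeric(flt$a), order = ord))
    }
  }
  stop("no stable Butterworth design for band (", lo, ", ", hi, ") Hz at fs ",
       fs, " Hz", call. = FALSE)
}

#' Band-pass filter an epoch set
#'
#' Applies one band-pass filter to every channel of every trial,
#' forward-backward (zero phase) by default.
#'
#' @param epochs an [epoch_set()].
#' @param band band as for [design_bandpass()].
#' @param order Butterworth prototype order.
#' @param zero_phase apply forward-backward?
#' @return A filtered `epoch_set` of identical shape.
#' @export
filter_epochs <- function(epochs, band, order = 4L, zero_phase = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  flt <- design_bandpass(band, epochs$fs, order)
  d <- dim(epochs$data)
  # column-major flatten: rows index (trial, channel), columns index samples
  X <- matrix(epochs$data, nrow = d[1L] * d[2L], ncol = d[3L])
  if (zero_phase) {
    Y <- cpp_filtfilt_rows(flt$b, flt$a, X)
  } else {
    Y <- t(apply(X, 1L, function(x) as.numeric(signal::filter(flt$b, flt$a, x))))
  }
  out <- array(Y, dim = d)
  epoch_set(out, epochs$labels, epochs$fs, epochs$t0, epochs$channels)
}

#' Decompose an epoch set through a filter bank
#'
#' @param epochs an [epoch_set()].
#' @param spec a [filter_bank_spec()].
#' @return A list of `epoch_set`, one per band, in band order; labels,
#'   sampling rate and shapes are carried through unchanged.
#' @export
apply_filterbank <- function(epochs, spec) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "filter_bank_spec"))
  lapply(seq_len(nrow(spec$bands)), function(i) {
    b <- spec$bands[i, ]
    tryCatch(
      filter_epochs(epochs, b, spec$order, spec$zero_phase),
      error = function(e)
        stop("band (", b$f_lo, ", ", b$f_hi, ") Hz: ", conditionMessage(e),
             call. = FALSE)
    )
  })
}

#' Slice epochs into time windows
#'
#' Cuts each trial to `[t_start, t_end)` relative to the cue, using half-open
#' 0-based sample indexing: sample `k` covers time `t0 + k/fs`, and a window
#' contains `round((t_end - t_start) * fs)` samples.
#'
#' @param epochs an [epoch_set()].
#' @param windows tibble with columns `t_start`, `t_end` or list of
#'   `c(start, end)` pairs, seconds.
#' @return A list of `epoch_set`, one per window.
#' @export
slice_time_windows <- function(epochs, windows) {
  stopifnot(inherits(epochs, "epoch_set"))
  windows <- as_window_tbl(windows)
  ns <- n_samples(epochs)
  lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    i0 <- round((w$t_start - epochs$t0) * epochs$fs)
    i1 <- round((w$t_end - epochs$t0) * epochs$fs)  # exclusive
    if (i0 < 0 || i1 > ns || i0 >= i1)
      stop("time window [", w$t_start, ", ", w$t_end, ") s lies outside the ",
           "epoch extent [", epochs$t0, ", ", epochs$t0 + ns / epochs$fs, ") s",
           call. = FALSE)
    epoch_set(epochs$data[, , (i0 + 1L):i1, drop = FALSE],
              epochs$labels, epochs$fs, w$t_start, epochs$channels)
  })
}

#' Default multi-scale time windows
#'
#' Three nested windows spanning the motor-imagery execution period of a
#' ~3 s trial: `[0.5, 3.5)`, `[0.5, 2.5)` and `[1.5, 3.5)` seconds post-cue.
#'
#' @param n how many of the three windows to take (1 keeps only the full
#'   `[0.5, 3.5)` window).
#' @return A tibble of time windows.
#' @export
default_time_windows <- function(n = 1L) {
  tw <- dplyr::bind_rows(time_window(0.5, 3.5), time_window(0.5, 2.5),
                         time_window(1.5, 3.5))
  tw[seq_len(n), ]
}
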