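#' Labeled multichannel EEG epochs
#'
#' Container for a set of EEG trials: a numeric array of shape
#' trials x channels x samples (microvolts), one integer class label per
#' trial, the sampling rate, and the time of the first sample relative to
#' the task cue.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, all finite.
#' @param labels integer-like vector of class labels, one per trial.
#' @param fs sampling rate in Hz (positive scalar).
#' @param t0 time of the first sample relative to the cue, in seconds.
#' @param channels optional character vector of channel names.
#' @return An object of class `epoch_set`.
#' @examples
#' x <- array(rnorm(2 * 3 * 100), dim = c(2, 3, 100))
#' ep <- epoch_set(x, labels = c(1, 2), fs = 100)
#' dim(ep$data)
#' @export
epoch_set <- function(data, labels, fs, t0 = 0, channels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials x channels x samples]", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L])
    stop("length(labels) must equal the number of trials", call. = FALSE)
  if (anyNA(labels))
    stop("`labels` contains missing values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (!is.null(channels) && length(channels) != dim(data)[2L])
    stop("length(channels) must equal the number of channels", call. = FALSE)
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         t0 = as.numeric(t0), channels = channels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$fs, x$t0))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials   <- function(x) dim(x$data)[1L]
n_channels <- function(x) dim(x$data)[2L]
n_samples  <- function(x) dim(x$data)[3L]

#' Subset trials of an epoch set
#'
#' @param x an [epoch_set()].
#' @param i trial index vector.
#' @return An `epoch_set` with the selected trials, in the requested order.
#' @export
subset_trials <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$labels[i], x$fs, x$t0, x$channels)
}

#' Summarize class balance
#'
#' @param x an [epoch_set()].
#' @return A tibble with one row per class: `label`, `n`.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  tab <- table(x$labels)
  tibble::tibble(label = as.integer(names(tab)), n = as.integer(tab))
}

# balanced-design check used by the pseudo-F contract
assert_balanced <- function(labels, min_per_class = 2L) {
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("at least 2 classes are required (single-class design is invalid)",
         call. = FALSE)
  if (length(unique(as.integer(tab))) != 1L)
    stop("unbalanced design: the distance-based pseudo-F assumes an equal ",
         "number of trials per class (got ",
         paste(sprintf("%s:%d", names(tab), tab), collapse = ", "), ")",
         call. = FALSE)
  if (tab[1L] < min_per_class)
    stop("need at least ", min_per_class, " trials per class", call. = FALSE)
  invisible(TRUE)
}

# trials-first array -> channels x samples x trials cube for the C++ kernels
epochs_to_cube <- function(x) aperm(x$data, c(2, 3, 1))
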