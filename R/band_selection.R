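#' Contiguous sub-band screening grid
#'
#' Splits `[f_min, f_max]` into contiguous non-overlapping bands of equal
#' width. The default grid — 2 Hz bands over 2-40 Hz — yields 19 sub-bands.
#'
#' @param f_min,f_max grid range in Hz.
#' @param width sub-band width in Hz; must divide `f_max - f_min`.
#' @return A tibble of bands (`f_lo`, `f_hi`), ascending.
#' @examples
#' nrow(subband_grid()) # 19
#' @export
subband_grid <- function(f_min = 2, f_max = 40, width = 2) {
  if (!(f_max > f_min) || width <= 0)
    stop("need f_min < f_max and width > 0", call. = FALSE)
  k <- (f_max - f_min) / width
  if (abs(k - round(k)) > 1e-9)
    stop("width ", width, " Hz does not divide the range [", f_min, ", ",
         f_max, "] Hz", call. = FALSE)
  lo <- f_min + width * (seq_len(round(k)) - 1L)
  tibble::tibble(f_lo = lo, f_hi = lo + width)
}

#' Pairwise distance matrix between trial covariances
#'
#' @param covs list of SPD matrices or an n x n x I array.
#' @param metric `"riemannian"` (geodesic, affine-invariant) or
#'   `"euclidean"` (Frobenius).
#' @return An I x I symmetric matrix with zero diagonal and attribute
#'   `metric`.
#' @export
pairwise_distance_matrix <- function(covs, metric = c("riemannian", "euclidean")) {
  metric <- match.arg(metric)
  P <- as_cov_cube(covs)
  if (dim(P)[3L] < 2L)
    stop("need at least 2 covariance matrices", call. = FALSE)
  D <- switch(metric,
              riemannian = cpp_airm_pairwise(P),
              euclidean  = cpp_eucl_pairwise(P))
  structure(D, metric = metric)
}

#' Distance-based one-way MANOVA pseudo-F
#'
#' A multivariate analog of Fisher's F computed directly from a pairwise
#' distance matrix (Anderson's non-parametric MANOVA). For a balanced design
#' of `a` classes with `n` trials each (`N = a * n`):
#' total sum of squares `SS_T = sum_{i<j} d_ij^2 / N`; within-class
#' `SS_W = sum_{i<j, same class} d_ij^2 / n`; between-class
#' `SS_A = SS_T - SS_W`; and `F = (SS_A / (a - 1)) / (SS_W / (N - a))`.
#' With Euclidean distances on univariate data this reduces exactly to the
#' classical one-way ANOVA F.
#'
#' @param D symmetric nonnegative distance matrix (zero diagonal).
#' @param labels class label per row of `D`; the design must be balanced.
#' @return A one-row tibble with columns `SS_T`, `SS_W`, `SS_A`, `F_stat`,
#'   `a`, `n`, `N`.
#' @examples
#' D <- as.matrix(dist(c(0, 1, 2, 3)))
#' pseudo_f(D, c(1, 1, 2, 2))$F_stat # 8
#' @export
pseudo_f <- function(D, labels) {
  if (!is_square(D))
    stop("`D` must be a square matrix", call. = FALSE)
  N <- nrow(D)
  if (length(labels) != N)
    stop("length(labels) must match nrow(D)", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 * max(abs(D), 1))
    stop("`D` must be symmetric", call. = FALSE)
  assert_balanced(labels)
  labels <- as.integer(factor(labels))
  a <- length(unique(labels))
  n <- N %/% a
  D2 <- D^2
  ut <- upper.tri(D2)
  same <- outer(labels, labels, "==")
  SS_T <- sum(D2[ut]) / N
  SS_W <- sum(D2[ut & same]) / n
  SS_A <- SS_T - SS_W
  if (SS_W <= .Machine$double.eps * max(SS_T, 1)) {
    warning("within-class sum of squares is zero; F is infinite", call. = FALSE)
    F_stat <- Inf
  } else {
    F_stat <- (SS_A / (a - 1)) / (SS_W / (N - a))
  }
  tibble::tibble(SS_T = SS_T, SS_W = SS_W, SS_A = SS_A, F_stat = F_stat,
                 a = a, n = n, N = N)
}

#' Score screening sub-bands by pseudo-F
#'
#' For each sub-band of the screening grid: band-pass filter the epochs,
#' estimate per-trial sample covariances, build the pairwise distance
#' matrix, and compute the distance-based pseudo-F. Bands are ranked in
#' descending F; ties break toward the lower frequency.
#'
#' @param epochs a labeled, class-balanced [epoch_set()].
#' @param grid tibble of sub-bands, e.g. [subband_grid()].
#' @param metric distance metric, as in [pairwise_distance_matrix()].
#' @param shrinkage covariance shrinkage fraction, see [estimate_scm()].
#' @param order Butterworth prototype order for the screening filters.
#' @return A `band_score_table`: tibble with columns `f_lo`, `f_hi`, `SS_T`,
#'   `SS_W`, `SS_A`, `F_stat`, `rank`.
#' @export
score_subbands <- function(epochs, grid = subband_grid(),
                           metric = c("riemannian", "euclidean"),
                           shrinkage = 0, order = 4L) {
  stopifnot(inherits(epochs, "epoch_set"))
  metric <- match.arg(metric)
  assert_balanced(epochs$labels)
  grid <- as_band_tbl(grid)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    b <- grid[i, ]
    res <- tryCatch({
      filtered <- filter_epochs(epochs, b, order = order)
      covs <- scm_set(filtered, shrinkage = shrinkage)
      D <- pairwise_distance_matrix(covs, metric)
      pseudo_f(D, epochs$labels)
    }, error = function(e)
      stop("sub-band (", b$f_lo, ", ", b$f_hi, ") Hz: ", conditionMessage(e),
           call. = FALSE))
    dplyr::bind_cols(b, res[c("SS_T", "SS_W", "SS_A", "F_stat")])
  })
  tbl <- dplyr::bind_rows(rows)
  ord <- order(-tbl$F_stat, tbl$f_lo)
  tbl$rank <- integer(nrow(tbl))
  tbl$rank[ord] <- seq_len(nrow(tbl))
  class(tbl) <- c("band_score_table", class(tbl))
  tbl
}

#' Select the top-G ranked sub-bands
#'
#' @param table a `band_score_table` from [score_subbands()].
#' @param G number of sub-bands to keep, `1 <= G <= nrow(table)`.
#' @return Tibble of the selected bands in ascending frequency order.
#' @export
select_top_g <- function(table, G) {
  if (G < 1 || G > nrow(table))
    stop("G must lie in [1, ", nrow(table), "]", call. = FALSE)
  sel <- table[table$rank <= G, c("f_lo", "f_hi")]
  dplyr::arrange(tibble::as_tibble(sel), .data$f_lo)
}

#' Merge adjacent sub-bands
#'
#' Fuses maximal runs of bands that share a boundary into single wider
#' bands. Idempotent; the output is ascending and pairwise non-adjacent.
#'
#' @param selected tibble of non-overlapping bands in ascending order.
#' @return Tibble of merged bands.
#' @examples
#' merge_adjacent(tibble::tibble(f_lo = c(8, 10, 20), f_hi = c(10, 12, 22)))
#' @export
merge_adjacent <- function(selected) {
  selected <- as_band_tbl(selected)
  if (nrow(selected) == 0L) stop("no bands to merge", call. = FALSE)
  selected <- dplyr::arrange(selected, .data$f_lo)
  lo <- selected$f_lo[1L]; hi <- selected$f_hi[1L]
  out <- list()
  for (i in seq_len(nrow(selected))[-1L]) {
    if (isTRUE(all.equal(selected$f_lo[i], hi))) {
      hi <- selected$f_hi[i]
    } else {
      out[[length(out) + 1L]] <- band_window(lo, hi)
      lo <- selected$f_lo[i]; hi <- selected$f_hi[i]
    }
  }
  out[[length(out) + 1L]] <- band_window(lo, hi)
  dplyr::bind_rows(out)
}

#' Multi-scale frequency-window scheme
#'
#' Window widths and hop sizes used to subdivide merged discriminative
#' bands into a multi-scale filter bank. The default — widths 2, 4, 8 Hz
#' with hops 2, 2, 4 Hz — generates 43 windows over the full 4-40 Hz parent
#' range, i.e. 43 x 253 = 10879 tangent features for 22 channels and one
#' time window.
#'
#' @param widths window widths in Hz.
#' @param hops hop (stride) per width in Hz; recycled against `widths`.
#' @return A tibble with columns `width`, `hop`.
#' @export
dmfb_scheme <- function(widths = c(2, 4, 8), hops = c(2, 2, 4)) {
  stopifnot(length(widths) == length(hops), all(widths > 0), all(hops > 0))
  tibble::tibble(width = as.numeric(widths), hop = as.numeric(hops))
}

#' Generate a discriminative multi-scale filter bank
#'
#' Enumerates, for each merged discriminative band, every frequency window
#' of the scheme that fits entirely inside the band; duplicates are removed
#' and ordering is deterministic (band, then width, then lower edge). A
#' merged band narrower than the smallest scheme width contributes itself
#' as a single window.
#'
#' @param merged tibble of merged bands from [merge_adjacent()].
#' @param scheme a [dmfb_scheme()].
#' @param order Butterworth prototype order for the resulting spec.
#' @return A [filter_bank_spec()] whose `bands` carry the generated windows.
#' @examples
#' nrow(generate_dmfb(band_window(4, 40))$bands) # 43
#' @export
generate_dmfb <- function(merged, scheme = dmfb_scheme(), order = 4L) {
  merged <- as_band_tbl(merged)
  if (nrow(merged) == 0L) stop("no merged bands supplied", call. = FALSE)
  windows <- purrr::map(seq_len(nrow(merged)), function(i) {
    lo <- merged$f_lo[i]; hi <- merged$f_hi[i]
    if (hi - lo < min(scheme$width) - 1e-9) {
      message("merged band (", lo, ", ", hi, ") Hz narrower than the smallest ",
              "scheme width; kept as a single window")
      return(band_window(lo, hi))
    }
    per_width <- purrr::map(seq_len(nrow(scheme)), function(s) {
      w <- scheme$width[s]; h <- scheme$hop[s]
      if (w > hi - lo + 1e-9) return(NULL)
      starts <- seq(lo, hi - w + 1e-9, by = h)
      tibble::tibble(f_lo = starts, f_hi = starts + w)
    })
    dplyr::bind_rows(per_width)
  })
  bands <- dplyr::distinct(dplyr::bind_rows(windows))
  filter_bank_spec(bands, order = order)
}
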