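#' Pipeline configuration
#'
#' Bundles every tunable of the decoding pipeline: screening grid,
#' multi-scale scheme, time windows, distance metric, covariance shrinkage,
#' the number of selected sub-bands G (fixed or chosen by cross-validation),
#' the SVM cost grid, and the RNG seed used for fold assignment.
#'
#' @param f_min,f_max,screen_width screening grid range and sub-band width,
#'   Hz (defaults: 2 Hz bands over 2-40 Hz, 19 sub-bands).
#' @param scheme multi-scale frequency-window scheme, see [dmfb_scheme()].
#' @param time_windows tibble of analysis time windows, seconds post-cue.
#' @param metric `"riemannian"` or `"euclidean"` distance for band scoring.
#' @param shrinkage covariance shrinkage fraction in `[0, 1)`.
#' @param G fixed number of selected sub-bands, or `NULL` to choose from
#'   `G_grid` by cross-validation on the training data.
#' @param G_grid candidate G values when `G` is `NULL`.
#' @param C_grid linear-SVM cost grid for cross-validated selection.
#' @param n_folds folds for hyperparameter cross-validation.
#' @param filter_order Butterworth prototype order.
#' @param seed RNG seed for fold assignment.
#' @return An object of class `mi_config` (a list).
#' @export
mi_config <- function(f_min = 2, f_max = 40, screen_width = 2,
                      scheme = dmfb_scheme(),
                      time_windows = default_time_windows(1),
                      metric = c("riemannian", "euclidean"),
                      shrinkage = 0, G = NULL, G_grid = 11:14,
                      C_grid = 10^(-3:2), n_folds = 10L,
                      filter_order = 4L, seed = 1L) {
  metric <- match.arg(metric)
  structure(list(
    f_min = f_min, f_max = f_max, screen_width = screen_width,
    scheme = scheme, time_windows = as_window_tbl(time_windows),
    metric = metric, shrinkage = shrinkage, G = G, G_grid = G_grid,
    C_grid = sort(C_grid), n_folds = as.integer(n_folds),
    filter_order = as.integer(filter_order), seed = as.integer(seed)
  ), class = "mi_config")
}

# run `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# stratified fold assignment; per-class fold sizes differ by <= 1
make_folds <- function(labels, k, seed) {
  if (min(table(labels)) < k)
    stop("stratified ", k, "-fold CV needs at least ", k, " trials per class",
         call. = FALSE)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

cell_key <- function(t_start, t_end, f_lo, f_hi)
  sprintf("t%.4f-%.4f_f%.4f-%.4f", t_start, t_end, f_lo, f_hi)

# per-cell tangent features: filter per band once, slice windows, SCM,
# reference (Karcher mean of the supplied trials unless given), tangent map.
# Returns an environment keyed by cell_key with list(features, reference).
compute_cells <- function(epochs, windows, bands, order, shrinkage,
                          references = NULL, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(bands))) {
    band <- bands[b, ]
    keys <- cell_key(windows$t_start, windows$t_end, band$f_lo, band$f_hi)
    if (all(vapply(keys, exists, logical(1), envir = cache))) next
    filtered <- filter_epochs(epochs, band, order = order)
    sliced <- slice_time_windows(filtered, windows)
    for (t in seq_len(nrow(windows))) {
      key <- keys[t]
      if (exists(key, envir = cache)) next
      covs <- tryCatch(
        scm_set(sliced[[t]], shrinkage = shrinkage),
        error = function(e)
          stop("cell [", windows$t_start[t], ", ", windows$t_end[t], ") s x (",
               band$f_lo, ", ", band$f_hi, ") Hz: ", conditionMessage(e),
               call. = FALSE))
      ref <- if (!is.null(references)) references[[key]]
      # 1e-7 on the (log-scale) gradient: narrow-band covariances of many
      # channels sit near the eigensolver precision floor at tighter values
      if (is.null(ref)) ref <- riemannian_mean(covs, tol = 1e-7,
                                               max_iter = 1000L)
      assign(key, list(features = tangent_space_map(covs, ref),
                       reference = ref), envir = cache)
    }
  }
  cache
}

#' Extract tangent-space features over a time-frequency grid
#'
#' For every (time window, frequency band) cell: band-pass filter the full
#' epochs, slice the window, estimate per-trial sample covariances, map them
#' to the tangent space at the cell's reference point (the Riemannian mean
#' of the supplied trials, unless `references` is given — as when applying
#' a trained model to test data), and concatenate the cell feature blocks.
#' Columns are ordered by time window, then band, then upper-triangle
#' position.
#'
#' @param epochs an [epoch_set()].
#' @param windows tibble of time windows.
#' @param dmfb a [filter_bank_spec()].
#' @param references optional named list of per-cell reference matrices from
#'   a previous call (training).
#' @param shrinkage covariance shrinkage fraction.
#' @return A list with `features` (trials x T*F*m matrix), `column_index`
#'   (tibble mapping each column to its window/band/triangle position), and
#'   `references` (named list, reusable on new data).
#' @export
extract_features <- function(epochs, windows, dmfb, references = NULL,
                             shrinkage = 0) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(dmfb, "filter_bank_spec"))
  windows <- as_window_tbl(windows)
  cache <- compute_cells(epochs, windows, dmfb$bands, dmfb$order, shrinkage,
                         references = references)
  assemble_features(cache, windows, dmfb$bands, n_channels(epochs))
}

# column order: time window major, then band, then triangle position
assemble_features <- function(cache, windows, bands, nc) {
  m <- nc * (nc + 1L) / 2L
  tri <- upper_index(nc)
  blocks <- list(); index <- list(); refs <- list()
  for (t in seq_len(nrow(windows))) {
    for (b in seq_len(nrow(bands))) {
      key <- cell_key(windows$t_start[t], windows$t_end[t],
                      bands$f_lo[b], bands$f_hi[b])
      cell <- get(key, envir = cache)
      blocks[[length(blocks) + 1L]] <- cell$features
      refs[[key]] <- cell$reference
      index[[length(index) + 1L]] <- tibble::tibble(
        window = t, t_start = windows$t_start[t], t_end = windows$t_end[t],
        f_lo = bands$f_lo[b], f_hi = bands$f_hi[b],
        row = tri$row, col = tri$col)
    }
  }
  list(features = do.call(cbind, blocks),
       column_index = dplyr::bind_rows(index),
       references = refs)
}

# ---- one-vs-rest linear SVM over SVD-compressed features -----------------

# decision value oriented so positive favors `pos_level`
ovr_decision <- function(model, x, pos_level) {
  dv <- attr(stats::predict(model, x, decision.values = TRUE),
             "decision.values")
  flip <- !startsWith(colnames(dv)[1L], paste0(pos_level, "/"))
  if (flip) -dv[, 1L] else dv[, 1L]
}

ovr_fit <- function(x, labels, cost) {
  classes <- sort(unique(labels))
  models <- lapply(classes, function(k) {
    y <- factor(ifelse(labels == k, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, y, type = "C-classification", kernel = "linear",
               cost = cost, scale = FALSE)
  })
  list(classes = classes, models = models, cost = cost)
}

ovr_predict <- function(fit, x) {
  dec <- vapply(fit$models, ovr_decision, numeric(nrow(x)), x = x,
                pos_level = "pos")
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1L)
  fit$classes[max.col(dec, ties.method = "first")]
}

# z-score parameters from training features; zero-variance columns pass through
scale_params <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}
apply_scale <- function(x, sp) sweep(sweep(x, 2L, sp$center), 2L, sp$scale, "/")

# CV accuracy of the OvR linear SVM for one cost, on precomputed folds.
# Features arrive already projected to the training row space, so each fold
# fit is cheap; the linear kernel is unchanged by the projection.
cv_accuracy <- function(x, labels, folds, cost) {
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    fit <- ovr_fit(x[tr, , drop = FALSE], labels[tr], cost)
    pred <- ovr_predict(fit, x[te, , drop = FALSE])
    correct <- correct + sum(pred == labels[te])
  }
  correct / length(labels)
}

#' Fit the discriminative multi-scale tangent-space decoder
#'
#' The full training procedure, on training data only: (1) score the 2 Hz
#' screening sub-bands with the distance-based pseudo-F; (2) keep the top G
#' sub-bands, merge adjacent ones, and expand the merged bands into a
#' multi-scale filter bank; (3) extract tangent-space features in every
#' time-frequency cell (reference = Riemannian mean of training trial
#' covariances); (4) z-score features and fit a one-vs-rest linear SVM with
#' cost C. G (when not fixed) and C are chosen jointly by stratified
#' cross-validation on the training set; per-cell features are shared across
#' G candidates, and the SVM works in an exact SVD compression of the
#' feature space (the linear kernel is preserved).
#'
#' @param train a labeled, class-balanced [epoch_set()].
#' @param cfg an [mi_config()].
#' @return An object of class `mi_tsm` with the band-score table, selected
#'   and merged bands, the generated filter bank, per-cell reference
#'   matrices, scaling parameters, the SVM, and the chosen G and C.
#' @export
mi_fit <- function(train, cfg = mi_config()) {
  stopifnot(inherits(train, "epoch_set"), inherits(cfg, "mi_config"))
  assert_balanced(train$labels)
  grid <- subband_grid(cfg$f_min, cfg$f_max, cfg$screen_width)
  scores <- score_subbands(train, grid, metric = cfg$metric,
                           shrinkage = cfg$shrinkage, order = cfg$filter_order)
  G_cands <- if (!is.null(cfg$G)) cfg$G else cfg$G_grid
  G_cands <- sort(unique(pmin(G_cands, nrow(grid))))
  plans <- lapply(G_cands, function(G) {
    merged <- merge_adjacent(select_top_g(scores, G))
    list(G = G, merged = merged,
         dmfb = generate_dmfb(merged, cfg$scheme, order = cfg$filter_order))
  })
  # shared per-cell feature cache across G candidates
  cache <- new.env(parent = emptyenv())
  for (p in plans)
    compute_cells(train, cfg$time_windows, p$dmfb$bands, cfg$filter_order,
                  cfg$shrinkage, cache = cache)
  folds <- make_folds(train$labels, cfg$n_folds, cfg$seed)
  nc <- n_channels(train)
  cv <- list()
  for (p in plans) {
    feat <- assemble_features(cache, cfg$time_windows, p$dmfb$bands, nc)
    sp <- scale_params(feat$features)
    z <- apply_scale(feat$features, sp)
    # exact compression: linear kernel on z equals linear kernel on z %*% V
    sv <- svd(z, nu = 0, nv = min(dim(z)))
    keep <- sv$d > sv$d[1L] * 1e-12
    x <- z %*% sv$v[, keep, drop = FALSE]
    for (C in cfg$C_grid)
      cv[[length(cv) + 1L]] <- tibble::tibble(
        G = p$G, C = C, cv_accuracy = cv_accuracy(x, train$labels, folds, C))
  }
  cv <- dplyr::bind_rows(cv)
  best <- cv[order(-cv$cv_accuracy, cv$G, cv$C), ][1L, ]
  plan <- plans[[match(best$G, G_cands)]]
  feat <- assemble_features(cache, cfg$time_windows, plan$dmfb$bands, nc)
  sp <- scale_params(feat$features)
  z <- apply_scale(feat$features, sp)
  sv <- svd(z, nu = 0, nv = min(dim(z)))
  keep <- sv$d > sv$d[1L] * 1e-12
  V <- sv$v[, keep, drop = FALSE]
  svm_fit <- ovr_fit(z %*% V, train$labels, best$C)
  structure(list(
    config = cfg, band_scores = scores, G = best$G, C = best$C,
    cv_table = cv, selected = select_top_g(scores, best$G),
    merged = plan$merged, dmfb = plan$dmfb,
    references = feat$references, column_index = feat$column_index,
    scaling = sp, projection = V, svm = svm_fit,
    classes = sort(unique(train$labels)),
    n_channels = nc, fs = train$fs, n_features = ncol(feat$features)
  ), class = "mi_tsm")
}

#' @export
print.mi_tsm <- function(x, ...) {
  cat("<mi_tsm> tangent-space motor-imagery decoder\n")
  cat(sprintf("  channels: %d @ %g Hz | classes: %s\n", x$n_channels, x$fs,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  G = %d selected sub-bands -> %d merged band(s) -> %d multi-scale window(s)\n",
              x$G, nrow(x$merged), nrow(x$dmfb$bands)))
  cat(sprintf("  %d time window(s) x %d bands x %d = %d tangent features; SVM C = %g\n",
              nrow(x$config$time_windows), nrow(x$dmfb$bands),
              x$n_channels * (x$n_channels + 1) / 2, x$n_features, x$C))
  invisible(x)
}

#' Predict motor-imagery class labels
#'
#' Features are extracted with the training references and scaling; the
#' stored one-vs-rest linear SVM assigns the class with the largest decision
#' value.
#'
#' @param object an `mi_tsm` model.
#' @param newdata an [epoch_set()] with the same channel count and sampling
#'   rate as the training data.
#' @param ... unused.
#' @return Integer vector of predicted labels, one per trial.
#' @export
predict.mi_tsm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "epoch_set"))
  if (n_channels(newdata) != object$n_channels)
    stop("channel count ", n_channels(newdata),
         " does not match the training data (", object$n_channels, ")",
         call. = FALSE)
  if (!isTRUE(all.equal(newdata$fs, object$fs)))
    stop("sampling rate ", newdata$fs, " Hz differs from training (",
         object$fs, " Hz); resampling is not supported", call. = FALSE)
  feat <- extract_features(newdata, object$config$time_windows, object$dmfb,
                           references = object$references,
                           shrinkage = object$config$shrinkage)
  z <- apply_scale(feat$features, object$scaling)
  ovr_predict(object$svm, z %*% object$projection)
}

#' Session-to-session transfer evaluation
#'
#' Fits the decoder on the training session and evaluates it on the test
#' session.
#'
#' @param train,test labeled [epoch_set()]s with identical label sets.
#' @param cfg an [mi_config()].
#' @param model optionally, an already-fitted `mi_tsm` to reuse.
#' @return An object of class `mi_eval`: list with `accuracy`, `per_class`
#'   (tibble), `confusion` (matrix, true x predicted), and the `model`.
#' @export
evaluate_session_transfer <- function(train, test, cfg = mi_config(),
                                      model = NULL) {
  if (!setequal(unique(train$labels), unique(test$labels)))
    stop("train and test label sets differ", call. = FALSE)
  if (is.null(model)) model <- mi_fit(train, cfg)
  pred <- predict(model, test)
  classes <- model$classes
  confusion <- table(factor(test$labels, levels = classes),
                     factor(pred, levels = classes))
  names(dimnames(confusion)) <- c("true", "predicted")
  per_class <- tibble::tibble(
    label = classes,
    n = as.integer(rowSums(confusion)),
    accuracy = diag(confusion) / pmax(rowSums(confusion), 1L))
  structure(list(accuracy = mean(pred == test$labels), per_class = per_class,
                 confusion = unclass(confusion), model = model),
            class = "mi_eval")
}

#' @export
print.mi_eval <- function(x, ...) {
  cat(sprintf("<mi_eval> accuracy %.1f%% over %d trials\n",
              100 * x$accuracy, sum(x$confusion)))
  print(x$per_class)
  invisible(x)
}

#' Stratified 10-fold cross-validation of the full pipeline
#'
#' Unlike the hyperparameter search inside [mi_fit()], this protocol redoes
#' *all* data-driven selection — band scoring, G, C, references, scaling —
#' inside each training fold, so held-out trials never influence the model.
#'
#' @param epochs a labeled, class-balanced [epoch_set()].
#' @param cfg an [mi_config()].
#' @param seed fold-assignment seed (defaults to `cfg$seed`).
#' @param k number of folds.
#' @return A list with `mean_accuracy` and `folds` (tibble: fold, n_test,
#'   accuracy).
#' @export
cross_validate_10fold <- function(epochs, cfg = mi_config(), seed = NULL,
                                  k = 10L) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(seed)) seed <- cfg$seed
  folds <- make_folds(epochs$labels, k, seed)
  res <- lapply(sort(unique(folds)), function(f) {
    tr <- subset_trials(epochs, which(folds != f))
    te <- subset_trials(epochs, which(folds == f))
    model <- mi_fit(tr, cfg)
    pred <- predict(model, te)
    tibble::tibble(fold = f, n_test = n_trials(te),
                   accuracy = mean(pred == te$labels))
  })
  folds_tbl <- dplyr::bind_rows(res)
  list(mean_accuracy = stats::weighted.mean(folds_tbl$accuracy,
                                            folds_tbl$n_test),
       folds = folds_tbl, fold_assignment = folds)
}

#' Save / load a fitted decoder
#'
#' @param model an `mi_tsm` model.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mi_tsm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mi_tsm"))
    stop("file does not contain an mi_tsm model archive", call. = FALSE)
  model
}
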