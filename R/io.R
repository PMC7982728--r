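#' Write an epoch set to disk
#'
#' Two container formats: `"rds"` (compact, default, chosen from a `.rds`
#' extension) and `"json"` (plain-text interchange; the data array is stored
#' flattened column-major together with its dimensions at full precision).
#' Both round-trip losslessly through [read_epochs()].
#'
#' @param epochs an [epoch_set()].
#' @param path output file; extension picks the format unless `format` is
#'   given.
#' @param format `"rds"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, format = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  format <- format %||% guess_format(path)
  switch(format,
    rds = saveRDS(epochs, path),
    json = {
      payload <- list(
        dim = dim(epochs$data), data = as.numeric(epochs$data),
        labels = epochs$labels, fs = epochs$fs, t0 = epochs$t0,
        channels = epochs$channels)
      # I(17) significant digits: bit-exact double round-trip through text
      jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                           null = "null")
    },
    stop("unsupported container format '", format, "'", call. = FALSE))
  invisible(path)
}

#' Read an epoch set from disk
#'
#' @param path input file.
#' @param format `"rds"`, `"json"`, or a standard EEG interchange format
#'   (`"gdf"`/`"edf"` — no adapter is bundled; a clear error is raised).
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  if (format %in% c("gdf", "edf"))
    stop("no GDF/EDF adapter is available in this installation; convert the ",
         "recording to the array container (rds/json) with external tooling",
         call. = FALSE)
  if (!format %in% c("rds", "json"))
    stop("unsupported container format '", format, "'", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    rds = {
      out <- readRDS(path)
      if (!inherits(out, "epoch_set"))
        stop("file does not contain an epoch_set container", call. = FALSE)
      out
    },
    json = {
      payload <- jsonlite::read_json(path, simplifyVector = TRUE)
      if (is.null(payload$labels))
        stop("container is missing trial labels", call. = FALSE)
      epoch_set(array(payload$data, dim = payload$dim), payload$labels,
                payload$fs, payload$t0 %||% 0, payload$channels)
    },
    stop("unsupported container format '", format, "'", call. = FALSE))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "") stop("cannot guess container format without an extension",
                      call. = FALSE)
  ext
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a band-score table as CSV
#'
#' Columns `f_lo, f_hi, SS_T, SS_W, SS_A, F, rank`, comma-separated with a
#' header row and `.` decimals.
#'
#' @param table a `band_score_table` from [score_subbands()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_scores <- function(table, path) {
  out <- data.frame(f_lo = table$f_lo, f_hi = table$f_hi, SS_T = table$SS_T,
                    SS_W = table$SS_W, SS_A = table$SS_A, F = table$F_stat,
                    rank = table$rank)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a band-score table written by [write_band_scores()]
#'
#' @param path CSV path.
#' @return A `band_score_table` tibble.
#' @export
read_band_scores <- function(path) {
  df <- utils::read.csv(path)
  tbl <- tibble::tibble(f_lo = df$f_lo, f_hi = df$f_hi, SS_T = df$SS_T,
                        SS_W = df$SS_W, SS_A = df$SS_A, F_stat = df$F,
                        rank = as.integer(df$rank))
  class(tbl) <- c("band_score_table", class(tbl))
  tbl
}

#' Serialize / restore a run configuration
#'
#' [mi_config()] and [sim_config()] round-trip through JSON so that every
#' run can write its resolved configuration beside its outputs.
#'
#' @param cfg an `mi_config` or `sim_config`.
#' @param path JSON path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   restored object.
#' @export
write_config <- function(cfg, path) {
  kind <- class(cfg)[1L]
  payload <- c(list(.kind = kind), unclass(cfg))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- payload$.kind
  payload$.kind <- NULL
  if (identical(kind, "mi_config")) {
    mi_config(
      f_min = payload$f_min, f_max = payload$f_max,
      screen_width = payload$screen_width,
      scheme = tibble::as_tibble(payload$scheme),
      time_windows = tibble::as_tibble(payload$time_windows),
      metric = payload$metric, shrinkage = payload$shrinkage,
      G = payload$G, G_grid = payload$G_grid, C_grid = payload$C_grid,
      n_folds = payload$n_folds, filter_order = payload$filter_order,
      seed = payload$seed)
  } else if (identical(kind, "sim_config")) {
    sim_config(
      n_classes = payload$n_classes,
      trials_per_class = payload$trials_per_class,
      n_channels = payload$n_channels, fs = payload$fs,
      duration = payload$duration, t0 = payload$t0,
      class_bands = tibble::as_tibble(payload$class_bands),
      class_gain = payload$class_gain,
      sources_per_class = payload$sources_per_class,
      background_exponent = payload$background_exponent,
      background_amplitude = payload$background_amplitude,
      n_background_sources = payload$n_background_sources,
      sensor_noise_sd = payload$sensor_noise_sd, seed = payload$seed)
  } else {
    stop("unknown configuration kind in ", path, call. = FALSE)
  }
}

#' Write evaluation metrics
#'
#' Emits `metrics.json` (accuracy, per-class accuracy, confusion matrix,
#' and provenance: chosen G, C, bands, seeds, package version) and
#' `confusion.csv` in an output directory.
#'
#' @param eval_result an `mi_eval`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_metrics <- function(eval_result, dir) {
  stopifnot(inherits(eval_result, "mi_eval"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model <- eval_result$model
  payload <- list(
    accuracy = eval_result$accuracy,
    per_class = eval_result$per_class,
    confusion = unclass(eval_result$confusion),
    provenance = list(
      package_version = as.character(utils::packageVersion("riembci")),
      G = model$G, C = model$C, seed = model$config$seed,
      metric = model$config$metric, shrinkage = model$config$shrinkage,
      merged_bands = model$merged, dmfb_bands = model$dmfb$bands,
      time_windows = model$config$time_windows,
      n_features = model$n_features))
  jsonlite::write_json(payload, file.path(dir, "metrics.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns", pretty = TRUE)
  cm <- as.data.frame.matrix(eval_result$confusion)
  utils::write.csv(cbind(true = rownames(cm), cm),
                   file.path(dir, "confusion.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
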