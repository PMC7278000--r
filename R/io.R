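# File interfaces: paired-readings CSV, dataset-spec YAML/JSON, ensemble
# JSON serialization. CSV dialect: comma-separated, UTF-8, '.' decimal,
# header `invasive_mgdl,noninvasive_mgdl`, values in mg/dl.

#' Read and write paired glucose readings as CSV
#'
#' The interchange format for paired readings: a two-column numeric CSV with
#' header `invasive_mgdl,noninvasive_mgdl`. Reading validates the header,
#' numeric parsing and positivity, naming the offending row on failure;
#' writing preserves full double precision so `read_pairs(write_pairs(d))`
#' is an exact round trip.
#'
#' @param path file path.
#' @return `read_pairs()`: a data frame of class `"paired_glucose"`.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = TRUE)
  need <- c("invasive_mgdl", "noninvasive_mgdl")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stopf("no paired readings in %s", path)
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stopf("non-numeric value in column `%s`, row %d", col, bad[1])
      v <- vn
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stopf("non-positive or missing glucose in column `%s`, row %d",
            col, bad[1])
    df[[col]] <- v
  }
  out <- df[, need]
  class(out) <- c("paired_glucose", "data.frame")
  attr(out, "provenance") <- sprintf("read from %s", path)
  out
}

#' @rdname read_pairs
#' @param data paired readings to write.
#' @export
write_pairs <- function(data, path) {
  df <- as.data.frame(data)[, c("invasive_mgdl", "noninvasive_mgdl")]
  # format() at 17 significant digits keeps the round trip exact
  df[] <- lapply(df, function(v) format(v, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write a dataset spec (YAML or JSON)
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_dataset_spec()`: a [dataset_spec()].
#' @export
read_dataset_spec <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  need <- c("n_pairs", "invasive_range", "noninvasive_range",
            "target_mard", "error_range")
  missing_fields <- setdiff(need, names(lst))
  if (length(missing_fields))
    stopf("spec file missing field(s): %s",
          paste(missing_fields, collapse = ", "))
  dataset_spec(lst$n_pairs, unlist(lst$invasive_range),
               unlist(lst$noninvasive_range), lst$target_mard,
               unlist(lst$error_range),
               name = if (is.null(lst$name)) "custom" else lst$name)
}

#' @rdname read_dataset_spec
#' @param spec a [dataset_spec()] to write.
#' @export
write_dataset_spec <- function(spec, path) {
  lst <- unclass(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

#' Serialize a boosted ensemble to JSON and back
#'
#' Writes the complete model state (node tables of every tree, confidences,
#' learning rate, loss kind, seed) so a fitted model can be reloaded
#' reproducibly without refitting.
#'
#' @param model a fitted [adaboost_r2()] model.
#' @param path file path.
#' @return `read_adaboost_json()`: the reconstructed `"adaboost_r2"` model.
#' @export
write_adaboost_json <- function(model, path) {
  stopifnot(inherits(model, "adaboost_r2"))
  payload <- list(
    type = "adaboost_r2",
    alpha = model$alpha, loss = model$loss,
    n_rounds = model$n_rounds, seed = model$seed,
    degenerate = model$degenerate,
    betas = model$betas,
    trees = lapply(model$trees, function(tr) {
      m <- tr$nodes
      list(left = m[, "left"], right = m[, "right"],
           threshold = m[, "threshold"], value = m[, "value"])
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_adaboost_json
#' @export
read_adaboost_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$type) || p$type != "adaboost_r2")
    stopf("not an adaboost_r2 model file: %s", path)
  rebuild <- function(tr) {
    nodes <- cbind(left = as.numeric(tr$left), right = as.numeric(tr$right),
                   threshold = as.numeric(tr$threshold),
                   value = as.numeric(tr$value))
    structure(list(nodes = nodes), class = "regtree1d")
  }
  trees <- if (is.data.frame(p$trees)) {
    lapply(seq_len(nrow(p$trees)), function(i)
      rebuild(lapply(p$trees, `[[`, i)))
  } else lapply(p$trees, rebuild)
  structure(list(trees = trees, betas = as.numeric(p$betas),
                 alpha = p$alpha, loss = p$loss,
                 n_rounds = as.integer(p$n_rounds),
                 seed = as.integer(p$seed),
                 degenerate = isTRUE(p$degenerate),
                 x = NULL, d = NULL),
            class = "adaboost_r2")
}

#' Write an evaluation report to files
#'
#' Writes the full report as JSON plus two CSVs mirroring the standard
#' result tables: the per-cluster error table and the Clarke zone summary
#' (measured and predicted side by side).
#'
#' @param report a [pgms_evaluate()] result.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir, prefix = "report") {
  stopifnot(inherits(report, "pgms_eval"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".json", "_clusters.csv",
                                           "_cega.csv")))
  payload <- list(clusters = report$clusters, overall = report$overall,
                  cega_initial = as.data.frame(report$cega_initial),
                  cega_final = as.data.frame(report$cega_final),
                  n = report$n)
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(report$clusters, paths[2], row.names = FALSE)
  cega <- data.frame(zone = report$cega_initial$zone,
                     measured_count = report$cega_initial$count,
                     measured_percent = report$cega_initial$percent,
                     predicted_count = report$cega_final$count,
                     predicted_percent = report$cega_final$percent)
  utils::write.csv(cega, paths[3], row.names = FALSE)
  invisible(paths)
}
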