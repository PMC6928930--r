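# CSV and JSON readers/writers.
#
# BPA CSV: header `t,<subset label>,...`, one row per time-step, absent
# columns meaning zero mass. Score CSV: header `t,<class>,...`. Report
# JSON: {"classes": [...], "precision": {class: value}, "recall": {...}}.
# Time indices are 0-based in files.

#' Read a stream of mass functions from CSV
#'
#' @param path CSV file with a leading `t` column and one column per
#'   subset label (`"|"`-joined element names; `"THETA"`/`"*"` for the
#'   full frame).
#' @param frame A [ds_frame()], or `NULL` to infer one from the header:
#'   elements are taken in order of first appearance across the subset
#'   labels.
#' @param renormalize Passed to [ds_mass()]: rescale rows whose masses do
#'   not sum to 1 instead of erroring.
#' @return A list of `ds_mass` objects with attribute `times` (the `t`
#'   column).
#' @export
read_bpa_csv <- function(path, frame = NULL, renormalize = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "t") {
    ds_stop("BPA CSV must start with a 't' column followed by subset columns")
  }
  labels <- names(df)[-1]
  if (is.null(frame)) frame <- infer_frame(labels)
  for (j in seq(2L, ncol(df))) {
    if (!is.numeric(df[[j]])) {
      ds_stop("non-numeric mass in column '", names(df)[j], "'")
    }
  }
  masses <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.numeric(df[i, -1])
    names(row) <- labels
    tryCatch(ds_mass(frame, row[row != 0], renormalize = renormalize),
             dsfuse_validation_error = function(e) {
               ds_stop("row ", i, " (t = ", df$t[i], "): ",
                       conditionMessage(e))
             })
  })
  attr(masses, "times") <- df$t
  attr(masses, "frame") <- frame
  masses
}

# frame from subset labels, elements in order of first appearance
infer_frame <- function(labels) {
  parts <- unlist(lapply(labels, function(l) {
    l <- trimws(l)
    if (l %in% c("THETA", "*")) character(0)
    else trimws(strsplit(l, "|", fixed = TRUE)[[1]])
  }))
  elements <- unique(parts)
  if (length(elements) == 0L) {
    ds_stop("cannot infer a frame from the header; pass one explicitly")
  }
  ds_frame(elements)
}

#' Write a stream of mass functions to CSV
#'
#' Columns are the union of focal subsets across the stream, in canonical
#' (bitmask) order; masses are serialized with 12 significant digits so a
#' read/write round trip preserves them to 1e-12.
#'
#' @param masses List of `ds_mass` objects on a shared frame.
#' @param path Output file path.
#' @param times Time indices; defaults to the `times` attribute of
#'   `masses`, else 0-based positions.
#' @export
write_bpa_csv <- function(masses, path, times = NULL) {
  if (is_mass(masses)) masses <- list(masses)
  if (length(masses) == 0L) ds_stop("nothing to write")
  lapply(masses, assert_mass)
  if (is.null(times)) times <- attr(masses, "times")
  if (is.null(times)) times <- seq_along(masses) - 1L
  df <- masses_to_df(masses, times)
  df[-1] <- lapply(df[-1], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a classifier score stream from CSV
#'
#' @param path CSV with a `t` column and one numeric score column per
#'   class.
#' @return A data frame.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) ds_stop("score CSV must have a 't' column")
  for (j in which(names(df) != "t")) {
    if (!is.numeric(df[[j]])) {
      ds_stop("non-numeric score in column '", names(df)[j], "'")
    }
  }
  df
}

#' Write a classifier score stream to CSV
#'
#' @param scores Data frame with a `t` column, as from
#'   [generate_stream()].
#' @param path Output file path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a classifier report from JSON
#'
#' Expected shape: `{"classes": [...], "precision": {class: value},
#' "recall": {class: value}}`, optionally `"accuracy"`.
#'
#' @param path JSON file path.
#' @return A [classifier_report()].
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (field in c("classes", "precision", "recall")) {
    if (is.null(obj[[field]])) {
      ds_stop("report JSON is missing field '", field, "'")
    }
  }
  classifier_report(classes = obj$classes,
                    precision = unlist(obj$precision),
                    recall = unlist(obj$recall),
                    accuracy = if (!is.null(obj$accuracy)) unlist(obj$accuracy))
}

#' Write a classifier report to JSON
#'
#' @param report A [classifier_report()].
#' @param path Output file path.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "classifier_report")) {
    ds_stop("expected a classifier_report object")
  }
  obj <- list(classes = report$classes,
              precision = as.list(report$precision),
              recall = as.list(report$recall))
  if (!is.null(report$accuracy)) obj$accuracy <- as.list(report$accuracy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stream configuration from YAML or JSON
#'
#' The file mirrors the arguments of [stream_config()]:
#' `segments` (each with `start`, `end`, `scores`), `noise_sd`,
#' `spike_prob`, `spike_target`, `spike_value`, `seed`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [stream_config()].
#' @export
read_stream_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(obj$segments)) ds_stop("config is missing 'segments'")
  if (is.null(obj$seed)) ds_stop("config is missing 'seed'")
  segments <- lapply(obj$segments, function(seg) {
    list(start = seg$start, end = seg$end, scores = unlist(seg$scores))
  })
  stream_config(segments = segments,
                noise_sd = obj$noise_sd %||% 0.05,
                spike_prob = obj$spike_prob %||% 0.02,
                spike_target = obj$spike_target,
                spike_value = obj$spike_value %||% 0.9,
                seed = obj$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
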