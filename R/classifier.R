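# Discounting classifier scores into mass functions.
#
# A softmax score vector says nothing about how often the classifier is
# wrong. Per-class precision and recall from a held-out confusion matrix do:
# of the frames the classifier calls class i, only precision_i are relevant,
# and of those only recall_i are correctly retrieved. Discounting each
# singleton score by precision_i * recall_i and moving the deficit to the
# full frame turns a raw score vector into a mass function whose mass on
# Theta is an explicit, honest statement of classifier ignorance.

#' Classifier report (per-class precision and recall)
#'
#' @param classes Ordered character vector of class names; fixes the frame.
#' @param precision,recall Numeric vectors in \[0, 1\], one value per class,
#'   either positional or named by class.
#' @param accuracy Optional per-class training accuracy, carried as
#'   metadata only — discounting uses precision and recall exclusively.
#' @return An object of class `classifier_report`.
#' @examples
#' classifier_report(c("Cocklebur", "Pigweed", "Ragweed"),
#'                   precision = c(0.94, 0.94, 0.96),
#'                   recall = c(1.0, 0.89, 0.94))
#' @export
classifier_report <- function(classes, precision, recall, accuracy = NULL) {
  frame <- ds_frame(classes)  # validates names
  align <- function(x, what) {
    if (!is.null(names(x))) {
      idx <- match(classes, names(x))
      if (anyNA(idx)) {
        ds_stop("missing ", what, " for class '", classes[which(is.na(idx))[1]], "'")
      }
      x <- x[idx]
    }
    x <- as.numeric(x)
    if (length(x) != length(classes)) {
      ds_stop("need one ", what, " value per class")
    }
    if (anyNA(x) || any(x < 0 | x > 1)) {
      ds_stop(what, " values must lie in [0, 1]")
    }
    stats::setNames(x, classes)
  }
  structure(list(classes = classes,
                 precision = align(precision, "precision"),
                 recall = align(recall, "recall"),
                 accuracy = if (!is.null(accuracy)) align(accuracy, "accuracy")),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Classifier report (", length(x$classes), " classes)\n", sep = "")
  df <- data.frame(precision = x$precision, recall = x$recall)
  if (!is.null(x$accuracy)) df$accuracy <- x$accuracy
  print(df)
  invisible(x)
}

SCORE_SUM_TOL <- 1e-9

#' Discount a score vector into a mass function
#'
#' Each singleton receives `precision_i * recall_i * score_i`; the deficit
#' `1 - sum` goes to the full frame as explicit ignorance. Raw scores are
#' used as-is (softmax output already sums to at most one); a shortfall in
#' the raw scores is likewise absorbed into the ignorance mass.
#'
#' @param scores Numeric score vector in \[0, 1\], one per class, summing
#'   to at most 1; positional in report class order, or named by class
#'   (case-sensitive, exact match).
#' @param report A [classifier_report()].
#' @return A `ds_mass` on the frame of the report's classes, with
#'   `m(THETA) >= 1 - sum(scores)`.
#' @examples
#' rep <- classifier_report(c("Cocklebur", "Pigweed", "Ragweed"),
#'                          precision = c(0.94, 0.94, 0.96),
#'                          recall = c(1.0, 0.89, 0.94))
#' bpa_from_scores(c(Ragweed = 1, Pigweed = 0, Cocklebur = 0), rep)
#' @export
bpa_from_scores <- function(scores, report) {
  if (!inherits(report, "classifier_report")) {
    ds_stop("expected a classifier_report object")
  }
  classes <- report$classes
  if (!is.null(names(scores))) {
    idx <- match(classes, names(scores))
    if (anyNA(idx)) {
      ds_stop("missing score for class '", classes[which(is.na(idx))[1]], "'")
    }
    scores <- scores[idx]
  }
  scores <- as.numeric(scores)
  if (length(scores) != length(classes)) ds_stop("need one score per class")
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    ds_stop("scores must lie in [0, 1]")
  }
  if (sum(scores) > 1 + SCORE_SUM_TOL) {
    ds_stop(sprintf("scores sum to %.6g > 1; not a softmax-like vector",
                    sum(scores)))
  }
  updated <- report$precision * report$recall * scores
  if (sum(updated) > 1 + SCORE_SUM_TOL) {
    ds_stop("discounted masses exceed 1; corrupt classifier report")
  }
  theta <- max(0, 1 - sum(updated))
  masses <- c(stats::setNames(updated, classes), THETA = theta)
  ds_mass(ds_frame(classes), masses[masses > 0], renormalize = TRUE)
}

#' Discount a whole score stream into mass functions
#'
#' Row-wise application of [bpa_from_scores()] to a score table, producing
#' a stream ready for [sliding_fuse()].
#'
#' @param scores A data frame with a `t` column and one numeric column per
#'   class of the report (extra columns are an error, as are missing ones).
#' @param report A [classifier_report()].
#' @return A list of `ds_mass` objects with attribute `times` (the `t`
#'   column).
#' @export
stream_to_bpas <- function(scores, report) {
  if (!inherits(report, "classifier_report")) {
    ds_stop("expected a classifier_report object")
  }
  if (!is.data.frame(scores)) ds_stop("scores must be a data frame")
  if (!"t" %in% names(scores)) ds_stop("score table must have a 't' column")
  missing <- setdiff(report$classes, names(scores))
  if (length(missing)) {
    ds_stop("score table is missing class column(s): ",
            paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(scores), c("t", report$classes))
  if (length(extra)) {
    ds_stop("score table has unknown column(s): ", paste(extra, collapse = ", "))
  }
  bpas <- lapply(seq_len(nrow(scores)), function(i) {
    row <- as.numeric(scores[i, report$classes])
    names(row) <- report$classes
    tryCatch(bpa_from_scores(row, report),
             dsfuse_validation_error = function(e) {
               ds_stop("row ", i, " (t = ", scores$t[i], "): ",
                       conditionMessage(e))
             })
  })
  attr(bpas, "times") <- scores$t
  bpas
}
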