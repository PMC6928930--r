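# Frame of discernment and bitmask subset encoding.
#
# Subsets of the frame are encoded as integer bitmasks: bit i (value 2^(i-1))
# is set iff the i-th hypothesis belongs to the subset. 0 encodes the empty
# set, 2^M - 1 the whole frame. Frames are capped at M = 20 so that masks fit
# comfortably in R's 32-bit integers and power-set enumeration stays tractable.

#' Create a frame of discernment
#'
#' A frame of discernment is the ordered, finite set of mutually exclusive
#' and exhaustive hypotheses over which evidence is expressed (for example
#' the weed species a classifier can report). The label order given here is
#' frozen: it fixes the bit assignment used internally for subsets and the
#' canonical column order of CSV output.
#'
#' @param labels Character vector of distinct, non-empty hypothesis names.
#'   Names may not contain `"|"` (the subset-label separator) and may not be
#'   the reserved aliases `"THETA"` or `"*"`. At most 20 hypotheses.
#' @return An object of class `ds_frame` with elements `labels` and `M`
#'   (the number of hypotheses).
#' @examples
#' ds_frame(c("A", "B", "C"))
#' @seealso [ds_mass()], [vacuous_mass()]
#' @export
ds_frame <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    ds_stop("a frame needs at least one hypothesis")
  }
  if (length(labels) > 20L) {
    ds_stop("frames with more than 20 hypotheses are not supported (got ",
            length(labels), ")")
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    ds_stop("hypothesis labels must be non-empty strings")
  }
  if (anyDuplicated(labels)) {
    ds_stop("duplicate hypothesis labels: ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(grepl("|", labels, fixed = TRUE))) {
    ds_stop("hypothesis labels may not contain '|'")
  }
  if (any(labels %in% c("THETA", "*"))) {
    ds_stop("'THETA' and '*' are reserved aliases for the full frame")
  }
  structure(list(labels = labels, M = length(labels)), class = "ds_frame")
}

#' @export
print.ds_frame <- function(x, ...) {
  cat("Frame of discernment (M = ", x$M, "): {",
      paste(x$labels, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# classed condition so the CLI can map validation failures to exit code 2
ds_stop <- function(...) {
  stop(structure(
    class = c("dsfuse_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_frame <- function(x) inherits(x, "ds_frame")

assert_frame <- function(x) {
  if (!is_frame(x)) ds_stop("expected a ds_frame object")
  invisible(x)
}

same_frame <- function(f1, f2) identical(f1$labels, f2$labels)

assert_same_frame <- function(f1, f2) {
  if (!same_frame(f1, f2)) {
    ds_stop("mass functions are defined on different frames")
  }
  invisible(TRUE)
}

theta_mask <- function(frame) as.integer(2^frame$M - 1)

# number of set bits for each mask in `bits`
mask_cardinality <- function(bits, frame) {
  single <- as.integer(2^(seq_len(frame$M) - 1L))
  vapply(bits, function(b) sum(bitwAnd(b, single) != 0L), integer(1))
}

#' Parse a subset label against a frame
#'
#' Subset labels are element names joined by `"|"` (e.g. `"A|B"`); the
#' aliases `"THETA"` and `"*"` denote the full frame. The empty set has no
#' label and cannot be parsed (mass on the empty set is always zero).
#'
#' @param frame A [ds_frame()].
#' @param label A single subset label.
#' @return Integer bitmask encoding the subset.
#' @export
parse_subset <- function(frame, label) {
  assert_frame(frame)
  if (length(label) != 1L || is.na(label)) {
    ds_stop("subset label must be a single string")
  }
  label <- trimws(label)
  if (label %in% c("THETA", "*")) return(theta_mask(frame))
  if (label == "" || label == "{}") {
    ds_stop("the empty set has no mass and no subset label")
  }
  parts <- trimws(strsplit(label, "|", fixed = TRUE)[[1]])
  idx <- match(parts, frame$labels)
  if (anyNA(idx)) {
    ds_stop("unknown hypothesis '", parts[which(is.na(idx))[1]],
            "' in subset label '", label, "'")
  }
  if (anyDuplicated(idx)) {
    ds_stop("repeated hypothesis in subset label '", label, "'")
  }
  as.integer(sum(2^(idx - 1L)))
}

#' Canonical label of a subset bitmask
#'
#' @param frame A [ds_frame()].
#' @param bits Integer bitmask (vectorised).
#' @return Character vector of labels, elements joined by `"|"` in frame
#'   order.
#' @export
subset_label <- function(frame, bits) {
  assert_frame(frame)
  single <- as.integer(2^(seq_len(frame$M) - 1L))
  vapply(as.integer(bits), function(b) {
    if (b <= 0L || b > theta_mask(frame)) {
      ds_stop("bitmask ", b, " does not encode a nonempty subset of the frame")
    }
    paste(frame$labels[bitwAnd(b, single) != 0L], collapse = "|")
  }, character(1))
}

# all nonempty subset masks, in increasing mask order
nonempty_masks <- function(frame) seq_len(theta_mask(frame))
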