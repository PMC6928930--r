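# Worked-example fixtures and the synthetic classification-stream generator.

#' Built-in worked-example fixtures
#'
#' The small evidence sets used throughout the documentation and tests.
#'
#' \describe{
#'   \item{`example1_m1`}{A sensor classifying among four targets
#'     \{a, b, c, d\} with two disjoint two-element focal sets:
#'     m(a,b) = 0.4, m(c,d) = 0.6. Returns a `ds_mass`.}
#'   \item{`example1_m2`}{A sensor classifying among three targets
#'     \{a, b, c\} whose focal sets share hypothesis c:
#'     m(a,c) = 0.4, m(b,c) = 0.6. Returns a `ds_mass`. Together with
#'     `example1_m1` this pair has identical Shannon and Deng entropies but
#'     different bound-based entropies — the discrimination the
#'     bound-based measure exists for.}
#'   \item{`example2`}{Five singleton BPAs over \{A, B, C\} in which four
#'     steps support A and the fourth step is adversarial (m(A) = 0,
#'     m(B) = 0.85): the anti-disturbance scenario. Returns an
#'     `evidence_window`.}
#'   \item{`example3`}{Five singleton BPAs over \{A, B, C\} in which the
#'     dominant target changes from A to B after the second step: the
#'     transition scenario. Returns an `evidence_window`.}
#'   \item{`table4_report`}{The weed classifier report: per-class precision
#'     (Cocklebur 0.94, Pigweed 0.94, Ragweed 0.96), recall (1.0, 0.89,
#'     0.94) and training accuracy 0.99. Returns a
#'     [classifier_report()].}
#' }
#'
#' @param name One of `"example1_m1"`, `"example1_m2"`, `"example2"`,
#'   `"example3"`, `"table4_report"`.
#' @return A `ds_mass`, `evidence_window` or `classifier_report`; see
#'   above.
#' @export
example_fixture <- function(name) {
  if (length(name) != 1L) ds_stop("fixture name must be a single string")
  abc <- ds_frame(c("A", "B", "C"))
  singleton_window <- function(rows) {
    evidence_window(lapply(rows, function(r) {
      ds_mass(abc, c(A = r[1], B = r[2], C = r[3]))
    }))
  }
  switch(name,
    example1_m1 = ds_mass(ds_frame(c("a", "b", "c", "d")),
                          c("a|b" = 0.4, "c|d" = 0.6)),
    example1_m2 = ds_mass(ds_frame(c("a", "b", "c")),
                          c("a|c" = 0.4, "b|c" = 0.6)),
    example2 = singleton_window(list(c(0.60, 0.10, 0.30),
                                     c(0.65, 0.15, 0.20),
                                     c(0.60, 0.20, 0.20),
                                     c(0.00, 0.85, 0.15),
                                     c(0.55, 0.20, 0.25))),
    example3 = singleton_window(list(c(0.60, 0.10, 0.30),
                                     c(0.65, 0.15, 0.20),
                                     c(0.20, 0.60, 0.20),
                                     c(0.10, 0.80, 0.10),
                                     c(0.15, 0.75, 0.10))),
    table4_report = classifier_report(
      classes = c("Cocklebur", "Pigweed", "Ragweed"),
      precision = c(0.94, 0.94, 0.96),
      recall = c(1.00, 0.89, 0.94),
      accuracy = c(0.99, 0.99, 0.99)),
    ds_stop("unknown fixture '", name, "'")
  )
}

#' Configure a synthetic classification stream
#'
#' Describes a piecewise-constant score stream with additive noise and
#' occasional adversarial spikes — the shape of per-frame softmax output
#' from a video classifier tracking plants: stretches dominated by one
#' class, jitter within a stretch, the odd wildly wrong frame, and gradual
#' transitions when the camera moves from one plant to the next.
#'
#' @param segments List of segments, each a list with `start` and `end`
#'   (0-based, half-open time indices) and `scores` (named baseline score
#'   vector in \[0, 1\] summing to at most 1). Segments must be contiguous
#'   and start at 0.
#' @param noise_sd Standard deviation of the zero-mean Gaussian noise added
#'   per class per step (then clipped to \[0, 1\] and rescaled if the sum
#'   exceeds 1). Non-negative.
#' @param spike_prob Per-step probability that the scores are replaced by
#'   an adversarial spike. In \[0, 1\].
#' @param spike_target Class receiving the spiked mass; must appear in the
#'   segment baselines. Required when `spike_prob > 0`.
#' @param spike_value Score given to `spike_target` in a spike step
#'   (default 0.9; other classes get 0).
#' @param seed Integer RNG seed; required, so that every stream is
#'   reproducible. No global RNG state is consumed.
#' @return An object of class `stream_config`.
#' @seealso [generate_stream()], [default_stream_config()]
#' @export
stream_config <- function(segments, noise_sd = 0.05, spike_prob = 0.02,
                          spike_target = NULL, spike_value = 0.9, seed) {
  if (missing(seed)) ds_stop("stream_config requires an explicit seed")
  seed <- as.integer(seed)
  if (is.na(seed)) ds_stop("seed must be an integer")
  if (!is.list(segments) || length(segments) == 0L) {
    ds_stop("need at least one segment")
  }
  classes <- NULL
  prev_end <- 0L
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    if (!all(c("start", "end", "scores") %in% names(seg))) {
      ds_stop("segment ", i, " needs fields start, end, scores")
    }
    if (seg$start != prev_end) {
      ds_stop("segments must be contiguous from 0: segment ", i,
              " starts at ", seg$start, ", expected ", prev_end)
    }
    if (seg$end <= seg$start) ds_stop("segment ", i, " has end <= start")
    sc <- seg$scores
    if (is.null(names(sc)) || any(!nzchar(names(sc)))) {
      ds_stop("segment ", i, " scores must be named by class")
    }
    if (any(sc < 0 | sc > 1) || sum(sc) > 1 + SCORE_SUM_TOL) {
      ds_stop("segment ", i, " baseline scores must lie in [0,1], sum <= 1")
    }
    if (is.null(classes)) classes <- names(sc)
    else if (!setequal(classes, names(sc))) {
      ds_stop("all segments must use the same classes")
    }
    prev_end <- seg$end
  }
  if (noise_sd < 0) ds_stop("noise_sd must be non-negative")
  if (spike_prob < 0 || spike_prob > 1) ds_stop("spike_prob must be in [0, 1]")
  if (spike_prob > 0) {
    if (is.null(spike_target)) ds_stop("spike_prob > 0 requires a spike_target")
    if (!spike_target %in% classes) {
      ds_stop("spike_target '", spike_target, "' is not a stream class")
    }
    if (spike_value < 0 || spike_value > 1) {
      ds_stop("spike_value must be in [0, 1]")
    }
  }
  structure(list(segments = segments, classes = classes,
                 noise_sd = noise_sd, spike_prob = spike_prob,
                 spike_target = spike_target, spike_value = spike_value,
                 seed = seed),
            class = "stream_config")
}

#' Default synthetic scenario
#'
#' A 200-step, three-class stream shaped like per-frame weed-classifier
#' output from a camera passing over two plants: 50 steps of confident
#' misclassification (the camera sees only the plant base), 70 noisy steps
#' of correct classification, a 30-step transition as the camera moves
#' between plants, and 50 steps on the second plant. Noise sd 0.05,
#' 2% adversarial spikes onto the class absent from the scene.
#'
#' @param seed RNG seed (default 42).
#' @return A [stream_config()].
#' @export
default_stream_config <- function(seed = 42) {
  stream_config(
    segments = list(
      list(start = 0L, end = 50L,
           scores = c(Ragweed = 0.20, Pigweed = 0.70, Cocklebur = 0.00)),
      list(start = 50L, end = 120L,
           scores = c(Ragweed = 0.80, Pigweed = 0.15, Cocklebur = 0.00)),
      list(start = 120L, end = 150L,
           scores = c(Ragweed = 0.45, Pigweed = 0.45, Cocklebur = 0.00)),
      list(start = 150L, end = 200L,
           scores = c(Ragweed = 0.10, Pigweed = 0.85, Cocklebur = 0.00))),
    noise_sd = 0.05, spike_prob = 0.02,
    spike_target = "Cocklebur", spike_value = 0.9,
    seed = seed)
}

#' Generate a synthetic classification-score stream
#'
#' Draws the stream described by a [stream_config()]: per step, the
#' segment baseline plus zero-mean Gaussian noise, clipped to \[0, 1\] and
#' rescaled to sum at most 1; with probability `spike_prob` the step is
#' instead an adversarial spike concentrating `spike_value` on the spike
#' target. Deterministic given the config seed; the caller's RNG state is
#' left untouched.
#'
#' @param config A [stream_config()].
#' @return A data frame with columns `t` (0-based) and one score column
#'   per class.
#' @export
generate_stream <- function(config) {
  if (!inherits(config, "stream_config")) {
    ds_stop("expected a stream_config object")
  }
  n <- max(vapply(config$segments, `[[`, numeric(1), "end"))
  k <- length(config$classes)
  # private RNG: restore whatever state the caller had
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  out <- matrix(0, nrow = n, ncol = k,
                dimnames = list(NULL, config$classes))
  for (seg in config$segments) {
    base <- seg$scores[config$classes]
    for (t in seq(seg$start, seg$end - 1L)) {
      spike <- config$spike_prob > 0 &&
        stats::runif(1) < config$spike_prob
      if (spike) {
        row <- stats::setNames(numeric(k), config$classes)
        row[config$spike_target] <- config$spike_value
      } else {
        row <- base
        if (config$noise_sd > 0) {
          row <- row + stats::rnorm(k, 0, config$noise_sd)
        }
        row <- pmin(pmax(row, 0), 1)
        if (sum(row) > 1) row <- row / sum(row)
      }
      out[t + 1L, ] <- row
    }
  }
  data.frame(t = seq_len(n) - 1L, out)
}
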