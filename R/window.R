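# The 8-step weighted time-domain fusion algorithm and streaming mode.
#
# Given an evidence window of N time-steps on one frame, the algorithm:
#   1. stacks the N mass functions (the multi-time-step information matrix);
#   2. computes all pairwise Jousselme distances;
#   3. sums distances per step (d_i) and 4. takes the global mean (d_bar);
#   5. computes the bound-based belief entropy of each step and normalizes;
#   6. partitions steps into credible (d_i <= d_bar) and incredible;
#   7. rewards credible steps with -ln(E_i) and penalizes incredible ones
#      with -ln(1 - E_i), normalizing jointly over all steps to weights;
#      then averages the window with those weights;
#   8. self-combines the weighted average (N - 1) times with Dempster's rule.
# Incredible steps (outliers in distance) get small weights, so a single
# adversarial frame cannot veto a hypothesis the rest of the window supports.

#' Build an evidence window
#'
#' An ordered sequence of mass functions on a shared frame — the
#' multi-time-step information matrix consumed by [fuse_window()].
#'
#' @param steps A list of [ds_mass()] objects (or a single mass) sharing
#'   one frame.
#' @return An object of class `evidence_window` with fields `frame` and
#'   `steps`.
#' @export
evidence_window <- function(steps) {
  if (is_mass(steps)) steps <- list(steps)
  if (!is.list(steps) || length(steps) == 0L) {
    ds_stop("an evidence window needs at least one mass function")
  }
  lapply(steps, assert_mass)
  frame <- steps[[1]]$frame
  for (s in steps[-1]) assert_same_frame(frame, s$frame)
  structure(list(frame = frame, steps = steps), class = "evidence_window")
}

#' @export
length.evidence_window <- function(x) length(x$steps)

#' @export
print.evidence_window <- function(x, ...) {
  cat("Evidence window: ", length(x$steps), " time-step(s) on {",
      paste(x$frame$labels, collapse = ", "), "}\n", sep = "")
  for (i in seq_along(x$steps)) {
    cat(sprintf("  t%d: %s\n", i - 1L, format(x$steps[[i]])))
  }
  invisible(x)
}

as_window <- function(x) {
  if (inherits(x, "evidence_window")) x else evidence_window(x)
}

#' Per-step sums of Jousselme distances
#'
#' `d[i]` is the summed distance from step `i` to every other step of the
#' window; large values flag steps in disagreement with the rest. A
#' single-step window returns `0`.
#'
#' @param window An [evidence_window()] (or list of masses).
#' @return Numeric vector of length N.
#' @export
distance_sums <- function(window) {
  window <- as_window(window)
  n <- length(window$steps)
  if (n == 1L) return(0)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      dm[i, j] <- dm[j, i] <-
        jousselme_distance(window$steps[[i]], window$steps[[j]])
    }
  }
  rowSums(dm)
}

#' Partition time-steps into credible and incredible
#'
#' A step is credible iff its distance sum does not exceed the window mean
#' (ties count as credible). Credible steps are in harmony with the window;
#' incredible steps are distance outliers and will be penalized.
#'
#' @param d Numeric vector of per-step distance sums.
#' @param d_bar The global average distance; defaults to `mean(d)`.
#' @return Logical vector: `TRUE` = credible.
#' @export
partition_credibility <- function(d, d_bar = mean(d)) {
  if (length(d) == 0L) ds_stop("empty distance vector")
  d <= d_bar
}

#' Normalized belief entropies of a window
#'
#' Per-step entropies scaled to sum to one. If every step is degenerate
#' (all entropies zero) the result falls back to the uniform vector — the
#' steps are then indistinguishable by entropy.
#'
#' @param window An [evidence_window()] (or list of masses).
#' @param measure Entropy measure, as in [belief_entropy()].
#' @return Numeric vector summing to 1.
#' @export
normalized_entropies <- function(window,
                                 measure = c("proposed", "shannon", "deng")) {
  window <- as_window(window)
  measure <- match.arg(measure)
  e <- vapply(window$steps, belief_entropy, numeric(1), measure = measure)
  s <- sum(e)
  if (s <= 0) return(rep(1 / length(e), length(e)))
  e / s
}

ENORM_CLAMP <- 1e-12

#' Reward/penalty weights from normalized entropies
#'
#' Credible steps are rewarded with `-ln(E[i])` (low normalized entropy =
#' concentrated, informative evidence = large reward); incredible steps are
#' penalized with `-ln(1 - E[i])`, which is small whenever `E[i] < 1/2`.
#' The raw values are normalized jointly over all steps — credible and
#' incredible pooled — to weights summing to one.
#'
#' @param e_norm Normalized entropies (sum 1), as from
#'   [normalized_entropies()]. Values are clamped to
#'   `[1e-12, 1 - 1e-12]` before taking logs.
#' @param credible Logical vector from [partition_credibility()].
#' @return Numeric weight vector, positive, summing to 1. If every raw
#'   value is zero the weights fall back to uniform.
#' @export
reward_penalty_weights <- function(e_norm, credible) {
  if (length(e_norm) != length(credible)) {
    ds_stop("entropy and credibility vectors differ in length")
  }
  e <- pmin(pmax(e_norm, ENORM_CLAMP), 1 - ENORM_CLAMP)
  raw <- ifelse(credible, -log(e), -log(1 - e))
  s <- sum(raw)
  if (s <= 0) return(rep(1 / length(raw), length(raw)))
  raw / s
}

#' Weighted average of an evidence window
#'
#' The modified evidence \eqn{\bar m(A) = \sum_i w_i m_i(A)} over every
#' subset focal in any step. A convex combination of valid mass functions,
#' hence itself valid.
#'
#' @param window An [evidence_window()] (or list of masses).
#' @param w Weights: non-negative, summing to 1, one per step.
#' @return A `ds_mass`.
#' @export
weighted_average_mass <- function(window, w) {
  window <- as_window(window)
  n <- length(window$steps)
  if (length(w) != n) ds_stop("need one weight per time-step")
  if (any(w < 0) || abs(sum(w) - 1) > MASS_SUM_TOL) {
    ds_stop("weights must be non-negative and sum to 1")
  }
  bits <- sort(unique(unlist(lapply(window$steps, `[[`, "bits"))))
  values <- numeric(length(bits))
  for (i in seq_len(n)) {
    values <- values + w[i] * mass_value(window$steps[[i]], bits)
  }
  keep <- values > 0
  new_ds_mass(window$frame, bits[keep], values[keep] / sum(values))
}

new_diagnostics <- function(d, d_bar, credible, e_norm, raw_weight, w) {
  structure(list(d = d, d_bar = d_bar, credible = credible,
                 e_norm = e_norm, raw_weight = raw_weight, w = w),
            class = "fusion_diagnostics")
}

#' @export
print.fusion_diagnostics <- function(x, digits = 4, ...) {
  cat("Fusion diagnostics (", length(x$d), " steps, mean distance ",
      round(x$d_bar, digits), "):\n", sep = "")
  print(data.frame(d = round(x$d, digits),
                   credible = x$credible,
                   e_norm = round(x$e_norm, digits),
                   weight = round(x$w, digits)))
  invisible(x)
}

#' Fuse an evidence window with the weighted time-domain algorithm
#'
#' Runs the full 8-step procedure (see the package vignette): Jousselme
#' distance sums, credibility partition at the mean distance, normalized
#' bound-based entropies, jointly normalized reward/penalty weights, the
#' weighted-average evidence, and finally `(N - 1)`-fold self-combination
#' of that average with Dempster's rule. The self-combination sharpens the
#' weighted average as plain sequential combination would, but because
#' every step entered the average with a weight, one adversarial step can
#' only dilute — never veto — the consensus.
#'
#' A single-step window is returned unchanged with trivial diagnostics.
#'
#' @param window An [evidence_window()] (or list of masses).
#' @param measure Entropy measure used for the weights (default
#'   `"proposed"`).
#' @return A list of class `fused_window`: `mass` (the fused `ds_mass`) and
#'   `diagnostics` (a `fusion_diagnostics` object: `d`, `d_bar`,
#'   `credible`, `e_norm`, `raw_weight`, `w`).
#' @examples
#' f <- ds_frame(c("A", "B", "C"))
#' w <- evidence_window(list(
#'   ds_mass(f, c(A = 0.6, B = 0.1, C = 0.3)),
#'   ds_mass(f, c(A = 0.65, B = 0.15, C = 0.2))))
#' fuse_window(w)$mass
#' @export
fuse_window <- function(window, measure = "proposed") {
  window <- as_window(window)
  n <- length(window$steps)
  if (n == 1L) {
    diag <- new_diagnostics(0, 0, TRUE, 1, 1, 1)
    return(structure(list(mass = window$steps[[1]], diagnostics = diag),
                     class = "fused_window"))
  }
  d <- distance_sums(window)
  d_bar <- mean(d)
  credible <- partition_credibility(d, d_bar)
  e_norm <- normalized_entropies(window, measure = measure)
  e <- pmin(pmax(e_norm, ENORM_CLAMP), 1 - ENORM_CLAMP)
  raw <- ifelse(credible, -log(e), -log(1 - e))
  w <- reward_penalty_weights(e_norm, credible)
  m_bar <- weighted_average_mass(window, w)
  fused <- m_bar
  for (k in seq_len(n - 1L)) fused <- dempster_combine(fused, m_bar)
  structure(list(mass = fused,
                 diagnostics = new_diagnostics(d, d_bar, credible,
                                               e_norm, raw, w)),
            class = "fused_window")
}

#' @export
print.fused_window <- function(x, ...) {
  cat("Fused window\n")
  print(x$mass)
  print(x$diagnostics)
  invisible(x)
}

#' Sliding-window fusion of an evidence stream
#'
#' Applies [fuse_window()] to the trailing `ts` steps at every position of
#' the stream. `ts` trades responsiveness (small windows track changes
#' fast) against robustness (large windows damp noise and adversarial
#' spikes). Before the window is full, the `warmup` policy decides what to
#' emit: `"grow"` (default) fuses the available prefix, so the output
#' starts with a 1-step window and grows to `ts`; `"passthrough"` emits the
#' raw input unchanged.
#'
#' @param stream List of [ds_mass()] objects on a shared frame (or an
#'   [evidence_window()]).
#' @param ts Window length in time-steps, `>= 1`. `ts = 1` reproduces the
#'   input stream.
#' @param warmup `"grow"` or `"passthrough"`.
#' @param measure Entropy measure, as in [fuse_window()].
#' @param times Optional numeric time indices (defaults to 0-based
#'   positions, matching the CSV convention).
#' @return An object of class `fused_stream`: `times`, `fused` (list of
#'   masses), `ts`, `warmup`, and `diagnostics` (per-position
#'   `fusion_diagnostics`, `NULL` where passthrough applied).
#' @export
sliding_fuse <- function(stream, ts, warmup = c("grow", "passthrough"),
                         measure = "proposed", times = NULL) {
  if (inherits(stream, "evidence_window")) stream <- stream$steps
  if (is_mass(stream)) stream <- list(stream)
  if (length(stream) == 0L) ds_stop("empty evidence stream")
  ts <- as.integer(ts)
  if (is.na(ts) || ts < 1L) ds_stop("window length ts must be >= 1")
  warmup <- match.arg(warmup)
  lapply(stream, assert_mass)
  frame <- stream[[1]]$frame
  for (s in stream[-1]) assert_same_frame(frame, s$frame)
  n <- length(stream)
  if (is.null(times)) times <- seq_len(n) - 1L
  if (length(times) != n) ds_stop("times must match the stream length")
  fused <- vector("list", n)
  diags <- vector("list", n)
  for (k in seq_len(n)) {
    if (k < ts && warmup == "passthrough") {
      fused[[k]] <- stream[[k]]
    } else {
      win <- stream[seq(max(1L, k - ts + 1L), k)]
      fw <- fuse_window(win, measure = measure)
      fused[[k]] <- fw$mass
      diags[[k]] <- fw$diagnostics
    }
  }
  structure(list(times = times, fused = fused, ts = ts, warmup = warmup,
                 diagnostics = diags),
            class = "fused_stream")
}

#' @export
length.fused_stream <- function(x) length(x$fused)

#' @export
print.fused_stream <- function(x, ...) {
  cat("Fused stream: ", length(x$fused), " step(s), ts = ", x$ts,
      ", warmup = ", x$warmup, "\n", sep = "")
  df <- as.data.frame(x)
  print(utils::head(round(df, 4), 10))
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more rows\n")
  invisible(x)
}

#' Convert a fused stream to a data frame of masses
#'
#' One row per time index, one column per subset focal anywhere in the
#' stream, plus a leading `t` column.
#'
#' @param x A `fused_stream`.
#' @param ... Unused.
#' @export
as.data.frame.fused_stream <- function(x, ...) {
  masses_to_df(x$fused, x$times)
}

# shared by as.data.frame and the CSV writer
masses_to_df <- function(masses, times) {
  frame <- masses[[1]]$frame
  bits <- sort(unique(unlist(lapply(masses, `[[`, "bits"))))
  cols <- lapply(bits, function(b) {
    vapply(masses, mass_value, numeric(1), bits = b)
  })
  df <- data.frame(t = times, cols)
  names(df) <- c("t", subset_label(frame, bits))
  df
}
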