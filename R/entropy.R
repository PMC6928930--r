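# Belief entropies and the Jousselme distance.
#
# All entropies are in bits (log base 2). The bound-based entropy uses the
# pignistic-like midpoint q(A) = (Bel(A) + Pl(A)) / 2 of each focal element,
# a cardinality factor (2^|A| - 1) as in Deng entropy, and a frame-size
# factor exp((|A| - 1) / M) so that the same focal structure carries more
# uncertainty on a larger frame. Only focal elements enter the sums.

#' Shannon entropy of a mass function
#'
#' Treats the focal-element masses as a discrete distribution:
#' \eqn{-\sum m(A) \log_2 m(A)}. For a Bayesian mass (all focal elements
#' singletons) this is the ordinary Shannon entropy of the class
#' probabilities; it ignores focal-element cardinality entirely.
#'
#' @param m A [ds_mass()].
#' @return Entropy in bits (non-negative).
#' @export
shannon_entropy <- function(m) {
  assert_mass(m)
  -sum(m$values * log2(m$values))
}

#' Deng entropy of a mass function
#'
#' \eqn{-\sum m(A) \log_2 (m(A) / (2^{|A|} - 1))}: Shannon entropy plus a
#' cardinality term crediting each focal element with its `2^|A| - 1`
#' nonempty sub-hypotheses. Reduces to [shannon_entropy()] on Bayesian
#' masses and never falls below it.
#'
#' @param m A [ds_mass()].
#' @return Entropy in bits (non-negative).
#' @export
deng_entropy <- function(m) {
  assert_mass(m)
  card <- mask_cardinality(m$bits, m$frame)
  -sum(m$values * log2(m$values / (2^card - 1)))
}

#' Bound-based belief entropy
#'
#' The entropy driving the reward/penalty weighting of [fuse_window()]:
#' \deqn{E_p = -\sum_{A\ focal} q(A) \log_2\!\left(\frac{q(A)}{2^{|A|}-1}
#'   \, e^{(|A|-1)/M}\right), \quad q(A) = \frac{Bel(A)+Pl(A)}{2}.}
#' Replacing the raw mass by the belief/plausibility midpoint makes the
#' measure sensitive to hypotheses shared between focal elements, and the
#' exponential factor makes it sensitive to the frame size M — two
#' situations in which Shannon and Deng entropy return identical values for
#' structurally different evidence. Reduces to [shannon_entropy()] on
#' Bayesian masses. Unlike the other two measures it is not bounded below
#' by zero across frames; compare values only between masses on stated
#' frames.
#'
#' @param m A [ds_mass()].
#' @return Entropy in bits.
#' @examples
#' m1 <- ds_mass(ds_frame(c("a", "b", "c", "d")),
#'               c("a|b" = 0.4, "c|d" = 0.6))
#' proposed_entropy(m1)  # 2.195: disjoint pairs on a 4-hypothesis frame
#' @export
proposed_entropy <- function(m) {
  assert_mass(m)
  card <- mask_cardinality(m$bits, m$frame)
  q <- vapply(m$bits, function(b) (bel(m, b) + pl(m, b)) / 2, numeric(1))
  terms <- ifelse(q > 0,
                  -q * log2(q / (2^card - 1) * exp((card - 1) / m$frame$M)),
                  0)
  sum(terms)
}

#' Belief entropy by measure name
#'
#' @param m A [ds_mass()].
#' @param measure One of `"proposed"` (default), `"shannon"`, `"deng"`.
#' @return Entropy in bits.
#' @export
belief_entropy <- function(m, measure = c("proposed", "shannon", "deng")) {
  measure <- match.arg(measure)
  switch(measure,
         proposed = proposed_entropy(m),
         shannon = shannon_entropy(m),
         deng = deng_entropy(m))
}

#' Jaccard similarity matrix over nonempty subsets
#'
#' The matrix \eqn{D_{AB} = |A \cap B| / |A \cup B|} over all `2^M - 1`
#' nonempty subsets of the frame, in increasing bitmask order. This is the
#' kernel of the Jousselme distance. Symmetric with unit diagonal and
#' entries in \[0, 1\] (exactly 0 between disjoint subsets).
#'
#' Dense construction is limited to frames with at most 10 hypotheses;
#' [jousselme_distance()] does not build this matrix and works on any
#' supported frame.
#'
#' @param frame A [ds_frame()].
#' @return A `(2^M - 1) x (2^M - 1)` numeric matrix with subset labels as
#'   dimnames.
#' @export
jaccard_matrix <- function(frame) {
  assert_frame(frame)
  if (frame$M > 10L) {
    ds_stop("dense Jaccard matrix is limited to frames with M <= 10")
  }
  masks <- nonempty_masks(frame)
  card <- mask_cardinality(masks, frame)
  n <- length(masks)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ic <- mask_cardinality(bitwAnd(masks[i], masks), frame)
    D[i, ] <- ic / (card[i] + card - ic)
  }
  dimnames(D) <- rep(list(subset_label(frame, masks)), 2)
  D
}

#' Jousselme distance between two mass functions
#'
#' \eqn{d(m_1, m_2) = \sqrt{\tfrac12 (v_1 - v_2) D (v_1 - v_2)^T}} where
#' `v` are the mass vectors over nonempty subsets and `D` the Jaccard
#' similarity matrix. A metric on mass functions with range \[0, 1\] that,
#' unlike a plain Euclidean distance, counts overlapping focal elements as
#' close. Computed sparsely on the union of focal elements.
#'
#' @param m1,m2 Mass functions on the same frame.
#' @return A value in \[0, 1\].
#' @examples
#' f <- ds_frame(c("A", "B", "C"))
#' jousselme_distance(ds_mass(f, c(A = 0.6, B = 0.1, C = 0.3)),
#'                    ds_mass(f, c(A = 0.65, B = 0.15, C = 0.2)))
#' @export
jousselme_distance <- function(m1, m2) {
  assert_mass(m1); assert_mass(m2)
  assert_same_frame(m1$frame, m2$frame)
  bits <- union(m1$bits, m2$bits)
  diff <- mass_value(m1, bits) - mass_value(m2, bits)
  nz <- diff != 0
  if (!any(nz)) return(0)
  bits <- bits[nz]; diff <- diff[nz]
  card <- mask_cardinality(bits, m1$frame)
  n <- length(bits)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ic <- mask_cardinality(bitwAnd(bits[i], bits), m1$frame)
    D[i, ] <- ic / (card[i] + card - ic)
  }
  val <- 0.5 * as.numeric(t(diff) %*% D %*% diff)
  if (val < 0) {
    if (val < -1e-12) ds_stop("negative squared distance: numerical failure")
    val <- 0
  }
  sqrt(val)
}
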