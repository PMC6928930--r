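# Mass functions (basic probability assignments) and Dempster's rule.

MASS_SUM_TOL <- 1e-9
FOCAL_DROP_TOL <- 1e-15
TOTAL_CONFLICT_TOL <- 1e-12

# internal constructor: bits/values assumed validated, positive, normalized
new_ds_mass <- function(frame, bits, values) {
  ord <- order(bits)
  structure(list(frame = frame,
                 bits = as.integer(bits[ord]),
                 values = as.numeric(values[ord])),
            class = "ds_mass")
}

#' Create a mass function (basic probability assignment)
#'
#' A mass function allocates unit belief mass over subsets of a frame of
#' discernment; subsets with positive mass are the focal elements. Mass on
#' the empty set is identically zero, and the masses must sum to one. Mass
#' on a non-singleton subset expresses ambiguity among its members rather
#' than support divided between them.
#'
#' @param frame A [ds_frame()].
#' @param masses Named numeric vector: names are subset labels (element
#'   names joined by `"|"`, or `"THETA"`/`"*"` for the full frame), values
#'   are non-negative masses. Zero entries are dropped; duplicate labels for
#'   the same subset are summed.
#' @param renormalize If `TRUE`, masses whose sum differs from 1 are scaled
#'   to sum to 1 instead of raising an error. The sum must still be
#'   positive.
#' @return An object of class `ds_mass` with fields `frame`, `bits`
#'   (focal-element bitmasks, increasing) and `values` (their masses).
#' @examples
#' f <- ds_frame(c("a", "b", "c"))
#' m <- ds_mass(f, c(a = 0.2, b = 0.3, "a|b" = 0.4, THETA = 0.1))
#' @export
ds_mass <- function(frame, masses, renormalize = FALSE) {
  assert_frame(frame)
  if (length(masses) == 0L) ds_stop("mass assignment is empty")
  if (is.null(names(masses)) || any(!nzchar(names(masses)))) {
    ds_stop("masses must be a fully named vector of subset labels")
  }
  values <- as.numeric(masses)
  if (anyNA(values) || any(!is.finite(values))) {
    ds_stop("masses must be finite numbers")
  }
  if (any(values < 0)) ds_stop("masses must be non-negative")
  bits <- vapply(names(masses), parse_subset, integer(1), frame = frame)
  # aggregate duplicate subsets (e.g. "A|B" and "B|A")
  agg <- rowsum(values, group = bits, reorder = TRUE)
  bits <- as.integer(rownames(agg))
  values <- as.numeric(agg)
  total <- sum(values)
  if (abs(total - 1) > MASS_SUM_TOL) {
    if (renormalize) {
      if (total <= 0) ds_stop("cannot renormalize: total mass is zero")
      values <- values / total
    } else {
      ds_stop(sprintf(
        "masses must sum to 1 (got %.12g); pass renormalize = TRUE to rescale",
        total))
    }
  }
  keep <- values > 0
  new_ds_mass(frame, bits[keep], values[keep])
}

#' Vacuous mass function (total ignorance)
#'
#' The mass function assigning all mass to the full frame. It expresses
#' complete ignorance and is the identity element of Dempster's rule.
#'
#' @param frame A [ds_frame()].
#' @return A `ds_mass` with the single focal element \eqn{\Theta}.
#' @export
vacuous_mass <- function(frame) {
  assert_frame(frame)
  new_ds_mass(frame, theta_mask(frame), 1)
}

is_mass <- function(x) inherits(x, "ds_mass")

assert_mass <- function(x) {
  if (!is_mass(x)) ds_stop("expected a ds_mass object")
  invisible(x)
}

as_mask <- function(frame, subset) {
  if (is.character(subset)) parse_subset(frame, subset)
  else {
    b <- as.integer(subset)
    if (is.na(b) || b < 0L || b > theta_mask(frame)) {
      ds_stop("subset mask out of range for this frame")
    }
    b
  }
}

#' @export
print.ds_mass <- function(x, digits = 4, ...) {
  cat("Mass function on {", paste(x$frame$labels, collapse = ", "), "}\n",
      sep = "")
  lab <- subset_label(x$frame, x$bits)
  lab[x$bits == theta_mask(x$frame)] <- "THETA"
  for (i in seq_along(lab)) {
    cat("  m(", lab[i], ") = ", format(round(x$values[i], digits)), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
format.ds_mass <- function(x, digits = 4, ...) {
  lab <- subset_label(x$frame, x$bits)
  paste0("m(", lab, ")=", round(x$values, digits), collapse = ", ")
}

# mass of an exact subset (0 if not focal)
mass_value <- function(m, bits) {
  i <- match(as.integer(bits), m$bits)
  ifelse(is.na(i), 0, m$values[i])
}

#' Belief of a subset
#'
#' `bel(m, A)` is the total mass committed to subsets of `A`: the lower
#' bound of support for `A`.
#'
#' @param m A [ds_mass()].
#' @param subset Subset label (or integer bitmask) over the same frame.
#' @return A value in \[0, 1\].
#' @examples
#' f <- ds_frame(c("a", "b", "c"))
#' m <- ds_mass(f, c("a|c" = 0.4, "b|c" = 0.6))
#' bel(m, "a|c")  # 0.4
#' @export
bel <- function(m, subset) {
  assert_mass(m)
  a <- as_mask(m$frame, subset)
  sum(m$values[bitwAnd(m$bits, a) == m$bits])
}

#' Plausibility of a subset
#'
#' `pl(m, A)` is one minus the belief in the complement of `A`: the total
#' mass that does not contradict `A`, and the upper bound of support.
#' `bel(m, A) <= pl(m, A)` always holds.
#'
#' @inheritParams bel
#' @return A value in \[0, 1\].
#' @export
pl <- function(m, subset) {
  assert_mass(m)
  a <- as_mask(m$frame, subset)
  if (a == 0L) return(0)
  sum(m$values[bitwAnd(m$bits, a) != 0L])
}

#' Conflict coefficient between two mass functions
#'
#' The total product mass placed on disjoint focal pairs: \eqn{K =
#' \sum_{B \cap C = \emptyset} m_1(B) m_2(C)}. `1 - K` is the normalizer of
#' Dempster's rule; `K = 1` means total conflict and the combination is
#' undefined.
#'
#' @param m1,m2 Mass functions on the same frame.
#' @return A value in \[0, 1\].
#' @export
conflict_k <- function(m1, m2) {
  assert_mass(m1); assert_mass(m2)
  assert_same_frame(m1$frame, m2$frame)
  inter <- outer(m1$bits, m2$bits, bitwAnd)
  prod <- outer(m1$values, m2$values)
  sum(prod[inter == 0L])
}

#' Combine two mass functions with Dempster's rule
#'
#' The conjunctive combination \eqn{m_{12}(A) = \sum_{B \cap C = A}
#' m_1(B) m_2(C) / (1 - K)}, which pools agreeing evidence and redistributes
#' the conflicting product mass `K` by normalization. The rule is
#' commutative and associative; the vacuous mass is its identity.
#'
#' Totally conflicting inputs (`K` = 1 within 1e-12) raise an error: the
#' combination is undefined there, and the weighted time-domain algorithm
#' ([fuse_window()]) exists precisely to avoid feeding such pairs to this
#' rule.
#'
#' @param m1,m2 Mass functions on the same frame.
#' @return The combined `ds_mass`. Focal elements whose combined mass falls
#'   below 1e-15 are dropped and the remainder renormalized, keeping focal
#'   sets sparse.
#' @examples
#' f <- ds_frame(c("A", "B", "C"))
#' t1 <- ds_mass(f, c(A = 0.6, B = 0.1, C = 0.3))
#' t2 <- ds_mass(f, c(A = 0.65, B = 0.15, C = 0.2))
#' dempster_combine(t1, t2)
#' @export
dempster_combine <- function(m1, m2) {
  assert_mass(m1); assert_mass(m2)
  assert_same_frame(m1$frame, m2$frame)
  inter <- as.vector(outer(m1$bits, m2$bits, bitwAnd))
  prod <- as.vector(outer(m1$values, m2$values))
  K <- sum(prod[inter == 0L])
  if (1 - K <= TOTAL_CONFLICT_TOL) {
    ds_stop("total conflict (K = 1): Dempster's rule is undefined")
  }
  keep <- inter != 0L
  agg <- rowsum(prod[keep], group = inter[keep], reorder = TRUE)
  bits <- as.integer(rownames(agg))
  values <- as.numeric(agg) / (1 - K)
  drop <- values < FOCAL_DROP_TOL
  if (any(drop)) {
    bits <- bits[!drop]
    values <- values[!drop]
    values <- values / sum(values)
  }
  new_ds_mass(m1$frame, bits, values)
}

#' Sequentially combine a list of mass functions
#'
#' Left fold of [dempster_combine()] over the list; by
#' commutativity/associativity the result is order-independent up to
#' floating-point tolerance.
#'
#' @param masses Non-empty list of `ds_mass` objects on a shared frame.
#' @return The combined `ds_mass`.
#' @export
sequential_combine <- function(masses) {
  if (is_mass(masses)) masses <- list(masses)
  if (length(masses) == 0L) ds_stop("cannot combine an empty list of masses")
  lapply(masses, assert_mass)
  Reduce(dempster_combine, masses)
}
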