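# Test helpers: random mass generation and brute-force oracles.
#
# The oracles deliberately avoid the package's bitmask machinery: subsets
# are character vectors of element names, and enumeration is exhaustive
# over the power set, so they stay independent of the code paths they
# check.

# all nonempty subsets of `labels` as a list of character vectors
all_subsets <- function(labels) {
  out <- list()
  for (k in seq_along(labels)) {
    out <- c(out, utils::combn(labels, k, simplify = FALSE))
  }
  out
}

subset_key <- function(els, labels) {
  paste(intersect(labels, els), collapse = "|")  # canonical frame order
}

# random mass with random focal subsets; returns a named vector usable by
# ds_mass() and by the oracles below. Always includes some mass on the full
# frame so that any two draws are combinable (K < 1), as the combination
# properties require.
rand_assignment <- function(labels, max_focal = 4L) {
  subs <- all_subsets(labels)
  subs <- subs[lengths(subs) < length(labels)]  # full frame added below
  n <- sample(seq_len(min(max_focal, length(subs))), 1L)
  pick <- c(sample(subs, n), list(labels))
  vals <- stats::rexp(n + 1L)
  vals <- vals / sum(vals)
  stats::setNames(vals, vapply(pick, subset_key, character(1),
                               labels = labels))
}

# brute-force Dempster combination over every pair of nonempty subsets
oracle_combine <- function(a1, a2, labels) {
  subs <- all_subsets(labels)
  keys <- vapply(subs, subset_key, character(1), labels = labels)
  v1 <- stats::setNames(numeric(length(keys)), keys)
  v2 <- v1
  v1[names(a1)] <- a1
  v2[names(a2)] <- a2
  out <- stats::setNames(numeric(length(keys)), keys)
  K <- 0
  for (i in seq_along(subs)) {
    for (j in seq_along(subs)) {
      p <- v1[i] * v2[j]
      if (p == 0) next
      inter <- intersect(subs[[i]], subs[[j]])
      if (length(inter) == 0L) K <- K + p
      else {
        key <- subset_key(inter, labels)
        out[key] <- out[key] + p
      }
    }
  }
  out <- out / (1 - K)
  out[out > 0]
}

# brute-force Jaccard similarity |A n B| / |A u B| between label subsets
oracle_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# named vector of a ds_mass's focal values, keyed by canonical label
mass_as_vector <- function(m) {
  stats::setNames(m$values, subset_label(m$frame, m$bits))
}

expect_mass_valid <- function(m) {
  expect_s3_class(m, "ds_mass")
  expect_true(all(m$values > 0))
  expect_true(all(m$bits >= 1L))
  expect_equal(sum(m$values), 1, tolerance = 1e-9)
}

# masses equal as set functions, within tol
expect_mass_equal <- function(m1, m2, tol = 1e-9) {
  bits <- union(m1$bits, m2$bits)
  v1 <- vapply(bits, function(b) dsfuse:::mass_value(m1, b), numeric(1))
  v2 <- vapply(bits, function(b) dsfuse:::mass_value(m2, b), numeric(1))
  expect_equal(v1, v2, tolerance = tol)
}

# Example 2 / Example 3 singleton windows, built fresh per call
abc_frame <- function() ds_frame(c("A", "B", "C"))

singleton_mass <- function(v) {
  ds_mass(abc_frame(), c(A = v[1], B = v[2], C = v[3]))
}
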