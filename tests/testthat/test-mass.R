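# Frame, mass-function and Dempster-rule algebra.

test_that("frame construction validates its labels", {
  f <- ds_frame(c("A", "B", "C"))
  expect_equal(f$M, 3L)
  expect_equal(f$labels, c("A", "B", "C"))

  expect_error(ds_frame(character(0)), "at least one")
  expect_error(ds_frame(c("A", "A")), "duplicate")
  expect_error(ds_frame(as.character(1:21)), "more than 20")
  expect_error(ds_frame(c("A", "")), "non-empty")
  expect_error(ds_frame(c("A", "B|C")), "may not contain")
  expect_error(ds_frame(c("A", "THETA")), "reserved")
})

test_that("subset labels parse to bitmasks and back", {
  f <- ds_frame(c("a", "b", "c"))
  expect_equal(parse_subset(f, "a"), 1L)
  expect_equal(parse_subset(f, "b"), 2L)
  expect_equal(parse_subset(f, "a|c"), 5L)
  expect_equal(parse_subset(f, "c|a"), 5L)   # order-insensitive
  expect_equal(parse_subset(f, "THETA"), 7L)
  expect_equal(parse_subset(f, "*"), 7L)
  expect_equal(subset_label(f, 5L), "a|c")   # canonical frame order
  expect_error(parse_subset(f, "{}"), "empty set")
  expect_error(parse_subset(f, ""), "empty set")
  expect_error(parse_subset(f, "a|z"), "unknown hypothesis 'z'")
  expect_error(parse_subset(f, "a|a"), "repeated")
})

test_that("mass construction enforces the normalization axiom", {
  f <- ds_frame(c("A", "B", "C"))
  m <- ds_mass(f, c(A = 0.6, B = 0.1, C = 0.3))
  expect_mass_valid(m)
  expect_equal(length(m$bits), 3L)

  # non-singleton focal elements are first-class
  f2 <- ds_frame(c("a", "b", "c"))
  m2 <- ds_mass(f2, c(a = 0.2, b = 0.3, "a|b" = 0.4, "a|b|c" = 0.1))
  expect_mass_valid(m2)
  expect_equal(length(m2$bits), 4L)

  expect_error(ds_mass(f, c(A = 0.5, B = 0.4)), "sum to 1")
  m3 <- ds_mass(f, c(A = 0.5, B = 0.4), renormalize = TRUE)
  expect_mass_valid(m3)
  expect_equal(bel(m3, "A"), 5 / 9, tolerance = 1e-12)

  expect_error(ds_mass(f, c(A = -0.1, B = 1.1)), "non-negative")
  expect_error(ds_mass(f, c(0.5, 0.5)), "named")
  # same subset under two spellings is aggregated, not duplicated
  m4 <- ds_mass(f2, c("a|b" = 0.5, "b|a" = 0.5))
  expect_equal(length(m4$bits), 1L)
})

test_that("vacuous mass is total ignorance", {
  f <- ds_frame(c("A", "B", "C"))
  v <- vacuous_mass(f)
  expect_mass_valid(v)
  expect_equal(bel(v, "THETA"), 1)
  for (s in c("A", "B", "C", "A|B", "A|C", "B|C")) {
    expect_equal(bel(v, s), 0)
    expect_equal(pl(v, s), 1)
  }
})

test_that("belief and plausibility bracket the committed mass", {
  m2 <- example_fixture("example1_m2")    # m(a,c)=0.4, m(b,c)=0.6
  expect_equal(bel(m2, "a|c"), 0.4)
  expect_equal(pl(m2, "a|c"), 1)          # complement {b} has no belief
  expect_equal(pl(m2, 0L), 0)             # empty set
  expect_equal(bel(m2, "THETA"), 1)

  # Bayesian: Bel on singletons is the mass itself
  f <- ds_frame(c("A", "B", "C"))
  mb <- ds_mass(f, c(A = 0.6, B = 0.1, C = 0.3))
  expect_equal(bel(mb, "A"), 0.6)
  expect_equal(pl(mb, "A"), 0.6)

  # interval property on random masses
  set.seed(11)
  labels <- c("a", "b", "c", "d")
  f4 <- ds_frame(labels)
  subs <- all_subsets(labels)
  for (i in 1:50) {
    m <- ds_mass(f4, rand_assignment(labels))
    for (s in subs) {
      key <- subset_key(s, labels)
      b <- bel(m, key); p <- pl(m, key)
      expect_gte(b, 0); expect_lte(p, 1)
      expect_lte(b, p + 1e-12)
    }
  }
})

test_that("conflict coefficient counts disjoint product mass", {
  f <- ds_frame(c("A", "B"))
  expect_equal(conflict_k(ds_mass(f, c(A = 1)), ds_mass(f, c(B = 1))), 1)
  expect_equal(conflict_k(vacuous_mass(f), vacuous_mass(f)), 0)
  m1 <- ds_mass(f, c(A = 0.6, B = 0.4))
  m2 <- ds_mass(f, c(A = 0.5, B = 0.5))
  expect_equal(conflict_k(m1, m2), 0.5)

  f3 <- ds_frame(c("A", "B", "C"))
  expect_error(conflict_k(m1, vacuous_mass(f3)), "different frames")
})

test_that("Dempster's rule matches worked values and handles edge cases", {
  f <- ds_frame(c("A", "B", "C"))
  t1 <- singleton_mass(c(0.6, 0.1, 0.3))
  t2 <- singleton_mass(c(0.65, 0.15, 0.2))
  m12 <- dempster_combine(t1, t2)
  expect_mass_valid(m12)
  # published 3-decimal values carry rounded intermediates: one ulp slack
  expect_equal(mass_as_vector(m12), c(A = 0.838, B = 0.032, C = 0.129),
               tolerance = 1.5e-3)

  # vacuous is the identity
  expect_mass_equal(dempster_combine(t1, vacuous_mass(f)), t1, tol = 1e-12)
  # totally conflicting singletons cannot be combined
  expect_error(
    dempster_combine(ds_mass(f, c(A = 1)), ds_mass(f, c(B = 1))),
    "total conflict")
})

test_that("combination is commutative and associative on random masses", {
  set.seed(7)
  labels <- c("a", "b", "c", "d")
  f <- ds_frame(labels)
  for (i in 1:30) {
    m1 <- ds_mass(f, rand_assignment(labels))
    m2 <- ds_mass(f, rand_assignment(labels))
    m3 <- ds_mass(f, rand_assignment(labels))
    expect_mass_equal(dempster_combine(m1, m2), dempster_combine(m2, m1),
                      tol = 1e-12)
    expect_mass_equal(
      dempster_combine(dempster_combine(m1, m2), m3),
      dempster_combine(m1, dempster_combine(m2, m3)),
      tol = 1e-9)
  }
})

test_that("combination agrees with the brute-force power-set oracle", {
  set.seed(13)
  for (labels in list(c("a", "b"), c("a", "b", "c"), c("a", "b", "c", "d"))) {
    f <- ds_frame(labels)
    for (i in 1:20) {
      a1 <- rand_assignment(labels)
      a2 <- rand_assignment(labels)
      got <- mass_as_vector(dempster_combine(ds_mass(f, a1), ds_mass(f, a2)))
      want <- oracle_combine(a1, a2, labels)
      expect_equal(got[order(names(got))], want[order(names(want))],
                   tolerance = 1e-9)
    }
  }
})

test_that("sequential combination folds the rule over a window", {
  win <- example_fixture("example2")
  # prefix T1..T3 and T1..T4: the one-ballot-veto failure appears at T4
  m3 <- sequential_combine(win$steps[1:3])
  expect_equal(mass_as_vector(m3), c(A = 0.939, B = 0.012, C = 0.048),
               tolerance = 1.5e-3)
  m4 <- sequential_combine(win$steps[1:4])
  expect_equal(dsfuse:::mass_value(m4, parse_subset(abc_frame(), "A")), 0)
  expect_equal(mass_as_vector(m4)[c("B", "C")], c(B = 0.586, C = 0.413),
               tolerance = 1.5e-3)

  # base case and validation
  expect_mass_equal(sequential_combine(win$steps[1]), win$steps[[1]])
  expect_error(sequential_combine(list()), "empty")
})
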