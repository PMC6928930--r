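# The 8-step weighted time-domain fusion algorithm and streaming mode.

test_that("distance sums flag the adversarial step", {
  win <- example_fixture("example2")
  d <- distance_sums(evidence_window(win$steps[1:4]))
  expect_equal(d, c(0.8740, 0.8130, 0.7765, 1.9903), tolerance = 5e-4)

  # two steps are equidistant from each other
  d2 <- distance_sums(evidence_window(win$steps[1:2]))
  expect_equal(d2[1], d2[2])
  # identical steps have zero distance everywhere
  expect_equal(distance_sums(evidence_window(rep(win$steps[1], 3))),
               rep(0, 3))
  expect_equal(distance_sums(evidence_window(win$steps[1])), 0)
})

test_that("credibility partition splits at the mean distance", {
  d <- c(0.8740, 0.8130, 0.7765, 1.9903)
  expect_equal(partition_credibility(d), c(TRUE, TRUE, TRUE, FALSE))
  # ties are credible, including the all-equal and single-step cases
  expect_equal(partition_credibility(c(0.3, 0.3, 0.3)), rep(TRUE, 3))
  expect_true(partition_credibility(0))
})

test_that("reward/penalty weights are jointly normalized", {
  e <- c(0.2844, 0.2808, 0.3010, 0.1339)
  w <- reward_penalty_weights(e, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(w, c(0.3247, 0.3281, 0.3101, 0.0371), tolerance = 5e-4)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # identical credible steps share weight equally
  expect_equal(reward_penalty_weights(rep(0.25, 4), rep(TRUE, 4)),
               rep(0.25, 4))
  # degenerate entropies survive the clamp
  expect_equal(sum(reward_penalty_weights(c(0, 1), c(TRUE, FALSE))), 1)
  expect_error(reward_penalty_weights(c(0.5, 0.5), TRUE), "length")
})

test_that("weighted average modifies the window evidence", {
  win <- example_fixture("example2")
  m <- weighted_average_mass(evidence_window(win$steps[1:2]),
                             c(0.4953, 0.5047))
  expect_equal(mass_as_vector(m), c(A = 0.6252, B = 0.1252, C = 0.2495),
               tolerance = 5e-4)
  expect_mass_valid(m)

  # uniform weights give the arithmetic mean
  mu <- weighted_average_mass(evidence_window(win$steps[1:2]), c(0.5, 0.5))
  expect_equal(mass_as_vector(mu),
               c(A = 0.625, B = 0.125, C = 0.25), tolerance = 1e-12)
  # single step with unit weight is the identity
  expect_mass_equal(
    weighted_average_mass(evidence_window(win$steps[1]), 1), win$steps[[1]])
  expect_error(weighted_average_mass(win, c(0.5, 0.5)), "one weight per")
  expect_error(
    weighted_average_mass(evidence_window(win$steps[1:2]), c(0.7, 0.7)),
    "sum to 1")
})

test_that("windowed fusion reproduces the worked anti-disturbance table", {
  win <- example_fixture("example2")
  printed <- list(`2` = c(A = 0.833, B = 0.033, C = 0.133),
                  `3` = c(A = 0.943, B = 0.017, C = 0.039),
                  `4` = c(A = 0.971, B = 0.007, C = 0.022),
                  `5` = c(A = 0.987, B = 0.002, C = 0.010))
  for (k in names(printed)) {
    fw <- fuse_window(evidence_window(win$steps[seq_len(as.integer(k))]))
    expect_mass_valid(fw$mass)
    expect_equal(sum(fw$diagnostics$w), 1, tolerance = 1e-9)
    # one ulp at the printed 3-decimal precision
    expect_equal(mass_as_vector(fw$mass), printed[[k]], tolerance = 1.5e-3)
  }
})

test_that("windowed fusion degenerates sensibly at small N", {
  win <- example_fixture("example2")
  # N = 1: identity with trivial diagnostics
  fw1 <- fuse_window(evidence_window(win$steps[1]))
  expect_mass_equal(fw1$mass, win$steps[[1]])
  expect_equal(fw1$diagnostics$w, 1)
  expect_true(fw1$diagnostics$credible)
  # N = 2 with identical inputs: weighted average is the input, so the
  # single self-combination must equal Dempster's rule on the pair
  m <- win$steps[[2]]
  fw2 <- fuse_window(evidence_window(list(m, m)))
  expect_mass_equal(fw2$mass, dempster_combine(m, m), tol = 1e-9)
})

test_that("fused support for the dominant target rises through a disturbance", {
  win <- example_fixture("example2")
  a_mask <- parse_subset(win$frame, "A")
  fused_a <- vapply(2:5, function(k) {
    dsfuse:::mass_value(fuse_window(evidence_window(win$steps[1:k]))$mass,
                        a_mask)
  }, numeric(1))
  # the adversarial step (m(A) = 0 at the 4th input) never dents m(A)
  expect_true(all(diff(fused_a) > 0))
  # while plain sequential Dempster is vetoed to zero by that same step
  expect_equal(
    dsfuse:::mass_value(sequential_combine(win$steps[1:4]), a_mask), 0)
})

test_that("incredible steps get the smallest weight in the worked windows", {
  win <- example_fixture("example2")
  for (k in 4:5) {
    dg <- fuse_window(evidence_window(win$steps[1:k]))$diagnostics
    if (any(!dg$credible) && all(dg$e_norm[!dg$credible] < 0.5)) {
      expect_lt(max(dg$w[!dg$credible]), min(dg$w[dg$credible]))
    }
  }
})

test_that("fused decision tracks a target transition within two steps", {
  win <- example_fixture("example3")
  argmax_of <- function(m) {
    labs <- subset_label(m$frame, m$bits)
    sing <- nchar(labs) == 1
    labs[sing][which.max(m$values[sing])]
  }
  raw_arg <- vapply(win$steps, argmax_of, character(1))
  expect_equal(raw_arg, c("A", "A", "B", "B", "B"))  # raw switch at step 3
  fused_arg <- vapply(seq_along(win$steps), function(k) {
    argmax_of(fuse_window(evidence_window(win$steps[1:k]))$mass)
  }, character(1))
  expect_equal(fused_arg[1], "A")
  # switched no later than two steps after the raw switch
  expect_equal(fused_arg[5], "B")
})

test_that("sliding fusion honors window length and warmup policy", {
  win <- example_fixture("example2")
  stream <- win$steps

  # ts = 1 reproduces the input
  fs1 <- sliding_fuse(stream, ts = 1)
  for (k in seq_along(stream)) expect_mass_equal(fs1$fused[[k]], stream[[k]])

  # constant stream gives time-invariant output once the window is full
  const <- rep(stream[2], 6)
  fsc <- sliding_fuse(const, ts = 3)
  for (k in 3:6) expect_mass_equal(fsc$fused[[k]], fsc$fused[[3]], tol = 1e-9)

  # grow fuses prefixes; passthrough emits raw input before the window fills
  fg <- sliding_fuse(stream, ts = 3, warmup = "grow")
  expect_mass_equal(fg$fused[[2]],
                    fuse_window(evidence_window(stream[1:2]))$mass)
  fp <- sliding_fuse(stream, ts = 3, warmup = "passthrough")
  expect_mass_equal(fp$fused[[2]], stream[[2]])
  expect_null(fp$diagnostics[[2]])
  # at and past ts - 1 the policies agree
  expect_mass_equal(fg$fused[[4]], fp$fused[[4]], tol = 1e-12)

  expect_error(sliding_fuse(stream, ts = 0), "ts must be >= 1")
  expect_error(sliding_fuse(list(), ts = 2), "empty")

  df <- as.data.frame(fg)
  expect_equal(df$t, 0:4)
  expect_true(all(abs(rowSums(df[-1]) - 1) < 1e-9))
})
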