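# Comparison statistics: relative differences, superiority probability,
# selection intensity, inbreeding rates.

test_that("relative difference uses the signed-base convention", {
  expect_equal(relative_difference(5, 5), 0)
  # negative base: the absolute value in the denominator keeps the sign
  # of the improvement
  expect_equal(relative_difference(1.5, -1.0), 2.5)
  expect_equal(relative_difference(30.11, 23.23), (30.11 - 23.23) / 23.23)
  expect_warning(rd0 <- relative_difference(1, 0))
  expect_true(is.na(rd0))
  # averaging order: mean of per-replicate ratios, not ratio of means
  a <- c(2, 9); b <- c(1, 10)
  per_rep <- mean(relative_difference(a, b))
  pooled <- (mean(a) - mean(b)) / abs(mean(b))
  expect_equal(per_rep, mean(c(1, -0.1)))
  expect_false(isTRUE(all.equal(per_rep, pooled)))
})

test_that("empirical probability reports the binomial SE, NE at the edges", {
  # p = 0.5 with n = 50: SE = sqrt(0.25/50)
  alt <- c(rep(1, 25), rep(0, 25)); base <- rep(0.5, 50)
  p <- empirical_probability(alt, base)
  expect_equal(p$p_hat, 0.5)
  expect_equal(p$se, 0.0707, tolerance = 1e-3)
  # all wins: probability 1, SE non-estimable
  p1 <- empirical_probability(2:11, 1:10)
  expect_equal(p1$p_hat, 1)
  expect_identical(p1$se_label, "NE")
  # strictness: ties do not count as wins
  pt <- empirical_probability(c(1, 1), c(1, 0))
  expect_equal(pt$p_hat, 0.5)
  # degenerate single replicate
  pd <- empirical_probability(2, 1)
  expect_identical(pd$se_label, "NE")
})

test_that("expected selection intensity matches a Monte-Carlo oracle", {
  # independent oracle: simulate order statistics directly
  set.seed(89)
  mc_intensity <- function(k, n, reps = 4e4) {
    mean(replicate(reps, mean(sort(stats::rnorm(n), decreasing = TRUE)[1:k])))
  }
  for (kn in list(c(2L, 10L), c(5L, 20L), c(1L, 8L))) {
    expect_equal(expected_selection_intensity(kn[1], kn[2]),
                 mc_intensity(kn[1], kn[2]), tolerance = 0.01)
  }
  expect_equal(expected_selection_intensity(7, 7), 0)
  expect_error(expected_selection_intensity(8, 7))
})

test_that("inbreeding rates divide the F change by years and generations", {
  tr <- data.frame(year = c(10, 20, 30), mean_F = c(0.02, 0.12, 0.22))
  r <- inbreeding_rates(tr, from = 10, to = 30, generations = 10)
  expect_equal(r$per_year, 0.01)
  expect_equal(r$per_generation, 0.02)
  flat <- data.frame(year = c(1, 2), mean_F = c(0.05, 0.05))
  r0 <- inbreeding_rates(flat, generations = 1)
  expect_equal(r0$per_year, 0)
  expect_equal(r0$per_generation, 0)
})

test_that("closed random mating approaches the haplodiploid drift rate", {
  # toy closed population: N dams and N DPQs drawn at random each
  # generation; the asymptotic inbreeding rate per generation should
  # approach 1/(2 Ne) with the haplodiploid effective size
  # Ne = 9 Nm Nf / (2 Nf + 4 Nm) (= 1.5 N for equal numbers)
  set.seed(97)
  N <- 12L
  n_gen <- 14L
  rate_reps <- replicate(6, {
    ped <- bee_pedigree()
    dams <- replicate(N, add_node(ped, "QUEEN", birth_year = 1))
    dpqs <- replicate(N, add_node(ped, "QUEEN", birth_year = 1))
    for (g in seq_len(n_gen)) {
      nd <- sample(dams, N, replace = TRUE)
      ns <- sample(dpqs, N, replace = TRUE)
      new_d <- mapply(function(d, s)
        add_node(ped, "QUEEN", dam = d, sire = s, birth_year = g + 1),
        sample(nd), sample(ns))
      new_s <- mapply(function(d, s)
        add_node(ped, "QUEEN", dam = d, sire = s, birth_year = g + 1),
        sample(nd), sample(ns))
      dams <- new_d; dpqs <- new_s
    }
    tr <- inbreeding_trajectory(ped)
    # asymptotic per-generation rate from the late panmictic decline of
    # (1 - F): 1 - F(t) ~ (1 - dF)^t
    lateF <- tr$mean_F[tr$year >= 6]
    fit <- stats::lm(log(1 - lateF) ~ seq_along(lateF))
    1 - exp(stats::coef(fit)[2])
  })
  Ne <- 9 * N * N / (2 * N + 4 * N)
  expect_equal(mean(rate_reps), 1 / (2 * Ne), tolerance = 0.2)
})
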