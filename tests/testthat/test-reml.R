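# REML variance estimation against dense-likelihood oracles.

test_that("REML matches the dense restricted likelihood optimum", {
  set.seed(61)
  dat <- toy_colony_data(n_dams = 16L, n_dpq = 8L, daughters = 10L,
                         params = genetic_params(r_T1T2 = 0.3),
                         missing_late = 12L)
  Ainv <- compute_A_inverse(dat$ped)
  est <- reml_estimate(dat$perf, Ainv, 0.9 * dat$G, 1.1 * dat$R, maxit = 300)
  # the package optimum cannot be improved upon by perturbing parameters
  # of the dense REML criterion (finite-difference stationarity / local
  # optimality within the PD cone)
  n2l0 <- dense_n2l(dat, est$G, est$R)
  expect_lt(n2l0, dense_n2l(dat, dat$G, dat$R) + 1e-6)  # beats the truth
  pert <- function(i, j, h, what = "G") {
    Gm <- est$G; Rm <- est$R
    if (what == "G") { Gm[i, j] <- Gm[i, j] + h; Gm[j, i] <- Gm[i, j] }
    else { Rm[i, j] <- Rm[i, j] + h; Rm[j, i] <- Rm[i, j] }
    dense_n2l(dat, Gm, Rm)
  }
  h <- 2e-3
  worst <- -Inf
  for (i in 1:4) for (j in i:4) {
    worst <- max(worst, n2l0 - pert(i, j, h), n2l0 - pert(i, j, -h))
  }
  for (i in 1:2) for (j in i:2) {
    worst <- max(worst, n2l0 - pert(i, j, h, "R"), n2l0 - pert(i, j, -h, "R"))
  }
  # no single-parameter move of size h may lower the criterion by more
  # than curvature-scale noise
  expect_lt(worst, 5e-4)
})

test_that("zero genetic variance drives estimates to the boundary", {
  set.seed(67)
  gp <- genetic_params()
  dat <- toy_colony_data(n_dams = 16L, n_dpq = 8L, daughters = 15L, params = gp)
  # overwrite phenotypes with pure noise: no genetic signal at all
  dat$perf$y_T1 <- stats::rnorm(nrow(dat$perf), 0, sqrt(gp$sigma2_eps))
  dat$perf$y_T2 <- stats::rnorm(nrow(dat$perf), 0, sqrt(gp$sigma2_eps))
  Ainv <- compute_A_inverse(dat$ped)
  # convergence at the boundary is not required; the estimates must
  # collapse toward zero relative to the residual scale
  est <- reml_estimate(dat$perf, Ainv, 0.9 * dat$G, 1.1 * dat$R, maxit = 120)
  expect_lt(max(diag(est$G)), 0.15 * max(diag(est$R)))
})

test_that("REML recovers known parameters from a simulated dataset", {
  set.seed(71)
  gp <- genetic_params()
  sim <- simulate_colony_data(gp, n_dams = 30L, daughters_per_dam = 20L,
                              n_generations = 3L, n_dpq = 30L)
  Ainv <- compute_A_inverse(sim$ped)
  est <- reml_estimate(sim$perf, Ainv, 0.9 * sim$G, 1.1 * sim$R)
  expect_true(est$converged)
  # single dataset of 1,800 records: generous sampling tolerance
  expect_equal(diag(est$G), diag(sim$G), tolerance = 0.35)
  expect_equal(diag(est$R), diag(sim$R), tolerance = 0.2)
  # likelihood trace is monotone up to step-control reverts
  ll <- est$logLik
  expect_gt(ll[length(ll)], ll[1])
})
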