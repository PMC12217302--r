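# True-breeding-value machinery: covariance construction, gametes,
# drones, queens, worker groups, colony phenotypes.

test_that("build_G forms the Kronecker covariance with the design ratios", {
  gp <- genetic_params()   # sigma2_AW = 1 -> AQ = 0.5, eps = 1.5
  expect_equal(gp$sigma2_AQ, gp$sigma2_AW / 2)
  expect_equal(gp$sigma2_AQ, gp$sigma2_eps / 3)
  G <- build_G(gp)
  expect_equal(unname(G), diag(c(1, 0.5, 1, 0.5)))

  # hand-multiplied Kronecker product with both correlations active
  gp2 <- genetic_params(r_WQ = -0.5, r_T1T2 = 0.6)
  G2 <- build_G(gp2)
  s_wq <- -0.5 * sqrt(1 * 0.5)
  expect_equal(G2["W1", "Q1"], s_wq, tolerance = 1e-12)
  expect_equal(round(G2["W1", "Q1"], 4), -0.3536)
  block <- matrix(c(1, s_wq, s_wq, 0.5), 2, 2)
  expect_equal(unname(G2[1:2, 3:4]), 0.6 * block)
  expect_gte(min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values), 0)

  # perfect between-trait correlation collapses the trait dimension
  gp3 <- genetic_params(r_T1T2 = 1)
  G3 <- build_G(gp3)
  expect_equal(qr(G3)$rank, 2L)
  expect_equal(unname(G3[1:2, 1:2]), unname(G3[1:2, 3:4]))
})

test_that("non-positive-definite parameter combinations are rejected", {
  # a correlation beyond [-1, 1] cannot even be constructed
  expect_error(genetic_params(r_T1T2 = 1.5))
  expect_error(genetic_params(sigma2_AW = -1))
})

test_that("founder draws have the base covariance and are reproducible", {
  gp <- genetic_params()
  G <- build_G(gp)
  set.seed(101)
  X <- draw_founder_bvs(G, 1e5)
  S <- stats::cov(X)
  # sampling SE of a variance at n = 1e5 is about sqrt(2/n) ~ 0.0045
  expect_lt(max(abs(S - G)), 3 * sqrt(2 / 1e5) * max(diag(G)) + 0.005)
  set.seed(42); a <- draw_founder_bvs(G, 24)
  set.seed(42); b <- draw_founder_bvs(G, 24)
  expect_identical(a, b)
  expect_equal(nrow(unique(a)), 24L)
  # degenerate case: no variance, no deviation
  expect_equal(unname(draw_founder_bvs(matrix(0, 4, 4), 3)),
               matrix(0, 3, 4))
})

test_that("gametes halve the parental value with (1-F)-scaled sampling variance", {
  gp <- genetic_params()
  G <- build_G(gp)
  bv <- c(2, -1, 0.5, 1)
  # fully inbred parent: gamete deterministic
  g1 <- make_gamete(bv, 1, G)
  expect_equal(drop(g1), 0.5 * bv)
  expect_error(make_gamete(bv, 1.2, G))
  # non-inbred parent: Var(deviation) ~ 0.25 G
  set.seed(7)
  gs <- make_gamete(matrix(bv, 1e5, 4, byrow = TRUE), 0, G)
  dev <- sweep(gs, 2, 0.5 * bv)
  expect_lt(max(abs(stats::cov(dev) - 0.25 * G)), 0.01)
  # Mendelian sampling variance is linear in (1 - F): regression of the
  # empirical variance on F recovers slope -0.25 * diag(G)
  Fs <- c(0, 0.25, 0.5, 1)
  v1 <- sapply(Fs, function(f) {
    g <- make_gamete(matrix(bv, 4e4, 4, byrow = TRUE), f, G)
    apply(g, 2, stats::var)
  })
  for (tr in 1:4) {
    slope <- stats::coef(stats::lm(v1[tr, ] ~ Fs))[2]
    expect_equal(unname(slope), -0.25 * G[tr, tr], tolerance = 0.05)
  }
})

test_that("variance closure: two independent gametes restore base variance", {
  gp <- genetic_params(r_WQ = -0.5, r_T1T2 = 0.3)
  G <- build_G(gp)
  set.seed(11)
  p1 <- draw_founder_bvs(G, 2e4)
  p2 <- draw_founder_bvs(G, 2e4)
  off <- make_gamete(p1, 0, G) + make_gamete(p2, 0, G)
  expect_lt(max(abs(stats::cov(off) - G)), 0.03)
})

test_that("drones are clonal gametes of their mother", {
  gp <- genetic_params()
  G <- build_G(gp)
  bv <- c(1, 2, 3, 4)
  # fully inbred DPQ: all drones identical
  dr <- make_drone(bv, 1, G, n = 10)
  expect_equal(unname(dr), matrix(0.5 * bv, 10, 4, byrow = TRUE))
  # variance among drones of a non-inbred DPQ ~ 0.25 G
  set.seed(13)
  dr2 <- make_drone(bv, 0, G, n = 4e4)
  expect_lt(max(abs(stats::cov(dr2) - 0.25 * G)), 0.01)
})

test_that("offspring queens combine a dam gamete with the full drone genome", {
  gp <- genetic_params()
  G <- build_G(gp)
  dam <- c(1, 0, -1, 2); drone <- c(0.2, 0.1, 0, -0.3)
  # deterministic when the dam is fully inbred
  off <- make_offspring_queen(dam, 1, drone, G)
  expect_equal(drop(off), 0.5 * dam + drone)
  # population moments: Var ~ G, Cov with dam ~ 0.5 G
  set.seed(17)
  dams <- draw_founder_bvs(G, 3e4)
  sires <- draw_founder_bvs(G, 3e4)
  drones <- make_gamete(sires, 0, G)
  offs <- make_offspring_queen(dams, 0, drones, G)
  expect_lt(max(abs(stats::cov(offs) - G)), 0.03)
  expect_lt(max(abs(stats::cov(offs, dams) - 0.5 * G)), 0.03)
})

test_that("super-sisters share 0.75 of additive variance (gene-level check)", {
  # same dam, same father drone: the paternal genome is identical
  gp <- genetic_params()
  G <- build_G(gp)
  set.seed(19)
  n <- 4e4
  dams <- draw_founder_bvs(G, n)
  sires <- draw_founder_bvs(G, n)
  drone <- make_gamete(sires, 0, G)         # one drone per pair
  s1 <- make_offspring_queen(dams, 0, drone, G)
  s2 <- make_offspring_queen(dams, 0, drone, G)
  cc <- diag(stats::cov(s1, s2)) / diag(G)
  expect_equal(unname(cc), rep(0.75, 4), tolerance = 0.05)
  # half-sisters through different drones of the same DPQ: 0.25 + 0.25/2
  d1 <- make_gamete(sires, 0, G); d2 <- make_gamete(sires, 0, G)
  h1 <- make_offspring_queen(dams, 0, d1, G)
  h2 <- make_offspring_queen(dams, 0, d2, G)
  ch <- diag(stats::cov(h1, h2)) / diag(G)
  expect_equal(unname(ch), rep(0.5, 4), tolerance = 0.05)
})

test_that("worker-group mean combines half the queen with equal drone shares", {
  gp <- genetic_params()
  G <- build_G(gp)
  q <- c(1, -2, 0, 1)
  d <- c(0.3, 0.2, -0.1, 0)
  wm <- worker_group_mean_bv(q, 0, matrix(d, 8, 4, byrow = TRUE))
  expect_equal(wm, 0.5 * q + d)
  expect_error(worker_group_mean_bv(q, 0, matrix(d, 5, 4, byrow = TRUE)))
  # paternal-term variance ~ (1/8) * 0.25 G across matings
  set.seed(23)
  n <- 3e4
  sires <- draw_founder_bvs(G, n)
  pat <- matrix(0, n, 4)
  for (k in 1:8) pat <- pat + make_gamete(sires, 0, G) / 8
  dev <- pat - 0.5 * sires
  expect_lt(max(abs(stats::cov(dev) - 0.25 * G / 8)), 0.01)
  # open-mated DPQ colony: base drones average to zero, so the expected
  # worker mean is half the DPQ value
  dpq <- c(2, 1, -1, 0)
  means <- replicate(4000, {
    dr <- draw_base_drones(8, G)
    worker_group_mean_bv(dpq, 0, dr)[1]
  })
  expect_equal(mean(means), 0.5 * dpq[1], tolerance = 3 * stats::sd(means) / sqrt(4000))
})

test_that("colony phenotypes decompose into genetic, apiary and residual parts", {
  gp <- genetic_params()
  G <- build_G(gp)
  # all variances zero: phenotype equals the sum of true effects
  gp0 <- genetic_params(sigma2_eps = 1e-12, sigma2_apiary = c(0, 0))
  qbv <- c(1, 2, 3, 4); wbv <- c(0.5, 0.5, 0.5, 0.5)
  y <- colony_phenotype(qbv, wbv, c(0, 0), gp0)
  expect_equal(unname(y[1, ]), c(2 + 0.5, 4 + 0.5), tolerance = 1e-5)
  # variance decomposition at base parameters
  set.seed(29)
  n <- 3e4
  qb <- draw_founder_bvs(G, n)
  wb <- 0.5 * qb + make_gamete(draw_founder_bvs(G, n), 0, G)
  E <- cbind(stats::rnorm(n, 0, sqrt(gp$sigma2_apiary[1])),
             stats::rnorm(n, 0, sqrt(gp$sigma2_apiary[2])))
  y <- colony_phenotype(qb, wb, E, gp)
  vg <- stats::var(qb[, 2] + wb[, 1])
  expect_equal(stats::var(y[, 1]), unname(vg + gp$sigma2_apiary[1] + gp$sigma2_eps),
               tolerance = 0.1)
  # early-only recording never produces a late value
  y2 <- colony_phenotype(qb[1:100, ], wb[1:100, ], E[1:100, ], gp,
                         traits_to_record = 1L)
  expect_true(all(is.na(y2[, 2])))
  expect_true(all(!is.na(y2[, 1])))
})
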