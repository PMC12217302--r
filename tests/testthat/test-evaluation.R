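# BLUP evaluation: MME assembly, dense GLS oracle, selection indices.

test_that("BLUP solution equals the dense GLS oracle (complete records)", {
  set.seed(43)
  dat <- toy_colony_data()
  sys <- build_mme(dat$perf, compute_A_inverse(dat$ped))
  fit <- solve_blup(sys, dat$G, dat$R)
  expect_lt(fit$resid_norm, 1e-8)
  ora <- dense_gls(dat)
  expect_lt(max(abs(fit$ebv - ora$ebv)), 1e-8)
})

test_that("BLUP handles missing late-trait records and matches the oracle", {
  set.seed(47)
  dat <- toy_colony_data(missing_late = 8L)
  sys <- build_mme(dat$perf, compute_A_inverse(dat$ped))
  fit <- solve_blup(sys, dat$G, dat$R)
  ora <- dense_gls(dat)
  expect_lt(max(abs(fit$ebv - ora$ebv)), 1e-8)
  # dams without late records still receive late-trait EBVs via relatives
  miss <- dat$perf$queen[is.na(dat$perf$y_T2)]
  expect_true(all(is.finite(fit$ebv[miss, c("W2", "Q2")])))
  expect_gt(max(abs(fit$ebv[miss, "Q2"])), 0)
})

test_that("single-record shrinkage matches the closed form", {
  # one colony, no fixed effects: the combined (worker + queen) EBV of
  # the record's own nodes shrinks the phenotype by the ratio of genetic
  # to phenotypic variance of the colony value
  gp <- genetic_params()
  G <- build_G(gp); R <- build_R(gp)
  ped <- bee_pedigree()
  q <- add_node(ped, "QUEEN")
  m <- add_node(ped, "QUEEN")
  w <- add_node(ped, "WORKER_GROUP", dam = q, sire = m)
  perf <- data.frame(queen = q, worker_group = w, apiary = 1, year = 1,
                     y_T1 = 2, y_T2 = NA)
  sys <- build_mme(perf, compute_A_inverse(ped), use_fixed = FALSE)
  fit <- solve_blup(sys, G, R)
  A <- compute_A(ped)$A
  # colony genetic value g = W(worker group) + Q(queen)
  var_g <- A[w, w] * G[1, 1] + A[q, q] * G[2, 2] + 2 * A[w, q] * G[1, 2]
  h2 <- var_g / (var_g + R[1, 1])
  expect_equal(unname(fit$ebv[w, "W1"] + fit$ebv[q, "Q1"]),
               unname(h2 * 2), tolerance = 1e-8)
})

test_that("row order of the performance file does not change the solution", {
  set.seed(53)
  dat <- toy_colony_data(missing_late = 5L)
  Ainv <- compute_A_inverse(dat$ped)
  f1 <- solve_blup(build_mme(dat$perf, Ainv), dat$G, dat$R)
  shuf <- dat$perf[sample(nrow(dat$perf)), ]
  f2 <- solve_blup(build_mme(shuf, Ainv), dat$G, dat$R)
  expect_lt(max(abs(f1$ebv - f2$ebv)), 1e-8)
})

test_that("selection indices weight summed worker+queen EBVs per trait", {
  ebv <- matrix(c(1, 0.5, -1, 0.2,
                  0, 1, 2, -0.5,
                  0.3, 0.3, 0.3, 0.3), 3, 4, byrow = TRUE)
  colnames(ebv) <- c("W1", "Q1", "W2", "Q2")
  # single-trait goal ranks only on trait 1
  i10 <- selection_index(ebv, 1:3, c(1, 0))
  expect_equal(i10, c(1.5, 1, 0.6))
  # hand-computed equal weights
  i55 <- selection_index(ebv, 1:3, c(0.5, 0.5))
  expect_equal(i55, c(0.5 * 1.5 + 0.5 * (-0.8),
                      0.5 * 1 + 0.5 * 1.5,
                      0.5 * 0.6 + 0.5 * 0.6))
  expect_warning(selection_index(ebv, 1:3, c(0.6, 0.4)), "grid")
  # dam and sire roles differ when own and worker-group EBVs differ:
  # scoring the worker-group row vs the queen's own row
  expect_false(isTRUE(all.equal(selection_index(ebv, 1, c(1, 0)),
                                selection_index(ebv, 2, c(1, 0)))))
})

test_that("index accuracy is the candidate-cohort correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(index_accuracy(x, x), 1)
  expect_equal(index_accuracy(x, -x), -1)
  expect_true(is.na(index_accuracy(x, rep(1, 5))))
  expect_error(index_accuracy(1, 1))
})

test_that("EBV selection beats phenotypic selection on identical data", {
  # with h^2 < 1 and family information, ranking candidates on BLUP EBVs
  # achieves at least the response of ranking on own phenotypes
  set.seed(59)
  wins <- 0; diffs <- numeric(20)
  for (s in 1:20) {
    dat <- toy_colony_data(n_dams = 8L, n_dpq = 4L, daughters = 8L,
                           params = genetic_params())
    sys <- build_mme(dat$perf, compute_A_inverse(dat$ped))
    fit <- solve_blup(sys, dat$G, dat$R)
    cand <- dat$perf[dat$perf$year == 2, ]
    true_val <- vapply(seq_len(nrow(cand)), function(i)
      dat$bv[[cand$queen[i]]][1] + dat$bv[[cand$queen[i]]][2], 1)
    ebv_idx <- fit$ebv[cand$queen, "W1"] + fit$ebv[cand$queen, "Q1"]
    phe_idx <- cand$y_T1
    k <- 8L
    resp_ebv <- mean(true_val[order(-ebv_idx)][1:k])
    resp_phe <- mean(true_val[order(-phe_idx)][1:k])
    diffs[s] <- resp_ebv - resp_phe
    if (resp_ebv >= resp_phe) wins <- wins + 1
  }
  expect_gt(mean(diffs), 0)
  expect_gte(wins, 13)
})
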