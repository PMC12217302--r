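# Design constants: configuration validation, mortality, apiary
# allocation, balanced matings.

test_that("configuration invariants are enforced", {
  cfg <- scheme_config(weights = c(0.5, 0.5))
  expect_equal(cfg$n_selected * cfg$offspring_per_dam, 432L)
  expect_error(scheme_config(weights = c(0.5, 0.5), n_apiaries = 17L),
               "apiar")
  expect_warning(scheme_config(weights = c(0.6, 0.4)), "grid")
  # 36-parent variant is feasible with sister groups of 12
  cfg36 <- scheme_config(weights = c(1, 0), n_selected = 36L,
                         offspring_per_dam = 12L)
  expect_equal(cfg36$n_selected * cfg36$offspring_per_dam, 432L)
})

test_that("mortality removes an exact random fraction", {
  set.seed(73)
  expect_length(apply_mortality(1:432, 0.25), 324L)
  expect_length(apply_mortality(1:324, 0.25), 243L)
  expect_identical(apply_mortality(1:100, 0), 1:100)
  expect_warning(apply_mortality(1:10, 0.26), "round")
  # removal is uniform: each id's survival frequency ~ 0.75
  surv <- numeric(20)
  for (r in 1:400) {
    s <- apply_mortality(1:20, 0.25)
    surv[s] <- surv[s] + 1
  }
  expect_lt(max(abs(surv / 400 - 0.75)), 4 * sqrt(0.25 * 0.75 / 400))
})

test_that("apiary allocation splits sister groups and fills apiaries evenly", {
  set.seed(79)
  ap <- allocate_apiaries(24L, 18L, 18L, 3L)
  expect_length(ap, 432L)
  grp <- rep(seq_len(24L), each = 18L)
  for (g in 1:24) {
    tab <- table(ap[grp == g])
    expect_length(tab, 3L)             # 3 distinct apiaries per group
    expect_true(all(tab == 6L))        # 6 sisters on each
  }
  expect_true(all(table(ap) == 24L))   # 24 queens per apiary (4 groups)
  expect_true(all(table(tapply(grp, ap, function(x) length(unique(x)))) > 0))
  # 36-parent variant: groups of 12 split 4/4/4, six groups per apiary
  ap36 <- allocate_apiaries(36L, 12L, 18L, 3L)
  expect_true(all(table(ap36) == 24L))
  expect_error(allocate_apiaries(24L, 18L, 17L, 3L), "infeasible")
  # marginal counts invariant under the label permutations
  ap2 <- allocate_apiaries(24L, 18L, 18L, 3L)
  expect_equal(sort(unname(table(ap2))), sort(unname(table(ap))))
})

test_that("matings are balanced across the selected drone sources", {
  set.seed(83)
  m <- mate_cohort(432L, 101:124)
  expect_true(all(table(m) == 18L))
  expect_setequal(unique(m), 101:124)
  expect_equal(unique(mate_cohort(10L, 7L)), 7L)
  expect_warning(mate_cohort(10L, 1:3), "balanced")
  # assignment is exchangeable: over many seeds, the DPQ mated to the
  # first queen is uniform over the pool
  firsts <- integer(24)
  for (s in 1:960) {
    a <- mate_cohort(48L, 1:24)
    firsts[a[1]] <- firsts[a[1]] + 1L
  }
  p <- stats::chisq.test(firsts)$p.value
  expect_gt(p, 1e-4)
})
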