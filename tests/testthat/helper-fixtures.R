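# Shared fixture builders and dense oracles for the test suite.

# Small hand-built pedigree exercising every node kind: founder queens,
# open matings (pseudo-sires), single-DPQ inseminations, worker groups,
# and one inbred queen (dam mated to her own sire DPQ).
toy_pedigree <- function() {
  ped <- bee_pedigree()
  ids <- list()
  ids$f1 <- add_node(ped, "QUEEN", birth_year = 1, label = "BQ1")
  ids$ps1 <- add_node(ped, "PSEUDO_SIRE", label = "PS1")
  ids$w1 <- add_node(ped, "WORKER_GROUP", dam = ids$f1, sire = ids$ps1)
  ids$dpq <- add_node(ped, "QUEEN", birth_year = 1, label = "DPQ1")
  ids$ps2 <- add_node(ped, "PSEUDO_SIRE", label = "PS2")
  ids$wd <- add_node(ped, "WORKER_GROUP", dam = ids$dpq, sire = ids$ps2)
  ids$q1 <- add_node(ped, "QUEEN", dam = ids$f1, sire = ids$ps1, birth_year = 2)
  ids$q2 <- add_node(ped, "QUEEN", dam = ids$f1, sire = ids$ps1, birth_year = 2)
  ids$q3 <- add_node(ped, "QUEEN", dam = ids$q1, sire = ids$dpq, birth_year = 3)
  ids$q4 <- add_node(ped, "QUEEN", dam = ids$q1, sire = ids$dpq, birth_year = 3)
  ids$w3 <- add_node(ped, "WORKER_GROUP", dam = ids$q3, sire = ids$dpq)
  ids$q5 <- add_node(ped, "QUEEN", dam = ids$q3, sire = ids$dpq, birth_year = 4)
  list(ped = ped, ids = ids)
}

# Random valid bee pedigree of roughly n nodes (queens, worker groups,
# pseudo-sires), for property tests.
random_pedigree <- function(n_target = 200L) {
  ped <- bee_pedigree()
  queens <- c(add_node(ped, "QUEEN"), add_node(ped, "QUEEN"),
              add_node(ped, "QUEEN"))
  dpqs <- add_node(ped, "QUEEN")
  while (ped$n < n_target) {
    u <- stats::runif(1)
    if (u < 0.5 && length(queens) >= 1) {
      dam <- sample(queens, 1)
      if (stats::runif(1) < 0.6 && length(dpqs) >= 1) {
        sire <- sample(dpqs, 1)
      } else {
        sire <- add_node(ped, "PSEUDO_SIRE")
      }
      if (dam == sire) next
      q <- add_node(ped, "QUEEN", dam = dam, sire = sire)
      if (stats::runif(1) < 0.3) dpqs <- c(dpqs, q) else queens <- c(queens, q)
    } else if (u < 0.8 && length(queens) >= 1) {
      q <- sample(queens, 1)
      sire <- if (stats::runif(1) < 0.5 && length(dpqs) >= 1 &&
                  !any(dpqs == q)) sample(setdiff(dpqs, q), 1)
              else add_node(ped, "PSEUDO_SIRE")
      if (length(sire)) add_node(ped, "WORKER_GROUP", dam = q, sire = sire)
    } else {
      queens <- c(queens, add_node(ped, "QUEEN"))
    }
  }
  ped
}

# Simulated two-generation colony dataset with true values, for BLUP /
# REML oracle checks. Returns pedigree, perf and truth.
toy_colony_data <- function(n_dams = 6L, n_dpq = 3L, daughters = 6L,
                            params = genetic_params(r_WQ = -0.5, r_T1T2 = 0.3),
                            missing_late = 0L) {
  G <- build_G(params); R <- build_R(params)
  ped <- bee_pedigree()
  bv <- list()
  fd <- integer(n_dams); dpq <- integer(n_dpq)
  for (i in seq_len(n_dams)) {
    fd[i] <- add_node(ped, "QUEEN", birth_year = 1)
    bv[[fd[i]]] <- drop(draw_founder_bvs(G, 1))
  }
  for (i in seq_len(n_dpq)) {
    dpq[i] <- add_node(ped, "QUEEN", birth_year = 1)
    bv[[dpq[i]]] <- drop(draw_founder_bvs(G, 1))
  }
  perf <- NULL
  n_ap <- 3L
  E <- matrix(stats::rnorm(2 * n_ap * 2, 0, sqrt(params$sigma2_apiary)),
              2 * n_ap, 2, byrow = FALSE)
  cell <- function(a, y) (y - 1) * n_ap + a
  for (i in seq_len(n_dams)) {
    m <- dpq[1 + (i %% n_dpq)]
    drones <- make_drone(bv[[m]], 0, G, n = 8)
    w <- add_node(ped, "WORKER_GROUP", dam = fd[i], sire = m)
    bv[[w]] <- worker_group_mean_bv(bv[[fd[i]]], 0, drones)
    perf <- rbind(perf, data.frame(queen = fd[i], worker_group = w,
                                   apiary = 1 + (i %% n_ap), year = 1))
    for (j in seq_len(daughters)) {
      dr <- drones[sample(8, 1), ]
      q <- add_node(ped, "QUEEN", dam = fd[i], sire = m, birth_year = 2)
      bv[[q]] <- drop(make_offspring_queen(bv[[fd[i]]], 0, dr, G))
      m2 <- dpq[1 + ((i + j) %% n_dpq)]
      dr2 <- make_drone(bv[[m2]], 0, G, n = 8)
      w2 <- add_node(ped, "WORKER_GROUP", dam = q, sire = m2)
      bv[[w2]] <- worker_group_mean_bv(bv[[q]], 0, dr2)
      perf <- rbind(perf, data.frame(queen = q, worker_group = w2,
                                     apiary = 1 + (j %% n_ap), year = 2))
    }
  }
  y <- t(sapply(seq_len(nrow(perf)), function(r) {
    colony_phenotype(bv[[perf$queen[r]]], bv[[perf$worker_group[r]]],
                     E[cell(perf$apiary[r], perf$year[r]), ], params)
  }))
  perf$y_T1 <- y[, 1]; perf$y_T2 <- y[, 2]
  if (missing_late > 0L) perf$y_T2[sample(nrow(perf), missing_late)] <- NA
  list(ped = ped, perf = perf, bv = bv, G = G, R = R, params = params)
}

# Dense GLS solution of the colony model (oracle for solve_blup).
dense_gls <- function(dat) {
  ped <- dat$ped
  A <- compute_A(ped)$A
  n <- ped$n
  Gam <- kronecker(A, dat$G)
  sys <- build_mme(dat$perf, compute_A_inverse(ped))
  obs <- sys$obs
  N <- nrow(obs)
  Z <- matrix(0, N, n * 4)
  for (r in seq_len(N)) {
    t <- obs$trait[r]
    Z[r, (obs$wg[r] - 1) * 4 + (2 * t - 1)] <- 1
    Z[r, (obs$queen[r] - 1) * 4 + (2 * t)] <- 1
  }
  X <- stats::model.matrix(~ 0 + factor(paste(obs$apiary, obs$year, obs$trait,
                                              sep = ":")))
  Sig <- matrix(0, N, N)
  for (cl in split(seq_len(N), obs$colony)) {
    tt <- obs$trait[cl]
    Sig[cl, cl] <- dat$R[tt, tt]
  }
  V <- Z %*% Gam %*% t(Z) + Sig
  Vi <- solve(V)
  bet <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% obs$y)
  uhat <- Gam %*% t(Z) %*% Vi %*% (obs$y - X %*% bet)
  list(ebv = matrix(uhat, nrow = n, ncol = 4, byrow = TRUE), obs = obs,
       Z = Z, X = X, A = A, Sig = Sig)
}

# Dense restricted -2 log likelihood of the colony model (oracle for
# reml_estimate): the profile-free REML criterion evaluated directly on
# the observation covariance matrix.
dense_n2l <- function(dat, Gm, Rm) {
  if (min(eigen(Gm, TRUE, TRUE)$values) < 1e-9 ||
      min(eigen(Rm, TRUE, TRUE)$values) < 1e-9) return(1e10)
  ora <- dense_gls(dat)
  obs <- ora$obs
  N <- nrow(obs)
  Gam <- kronecker(ora$A, Gm)
  Sig <- matrix(0, N, N)
  for (cl in split(seq_len(N), obs$colony)) {
    tt <- obs$trait[cl]
    Sig[cl, cl] <- Rm[tt, tt]
  }
  V <- ora$Z %*% Gam %*% t(ora$Z) + Sig
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(1e10)
  Vi <- chol2inv(cv)
  XVX <- t(ora$X) %*% Vi %*% ora$X
  b <- solve(XVX, t(ora$X) %*% Vi %*% obs$y)
  r_ <- obs$y - ora$X %*% b
  as.numeric(2 * sum(log(diag(cv))) + determinant(XVX)$modulus +
               t(r_) %*% Vi %*% r_)
}

# fast config for engine tests: full cohort design, shorter horizon
short_config <- function(weights = c(1, 0), end_year = 16L, ...) {
  scheme_config(weights = weights, params = genetic_params(),
                end_year = end_year, evaluation = "known", ...)
}
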