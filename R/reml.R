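#' REML estimation of the colony-model variance components
#'
#' Estimates the genetic covariance matrix of the worker and queen effects
#' (over the traits present in the data) and the residual covariance by
#' restricted maximum likelihood, using average-information updates with
#' expectation-maximization fallback steps. All traces are computed
#' exactly from the selected inverse of the mixed-model coefficient matrix
#' (Takahashi equations on the sparse Cholesky factor); no Monte-Carlo
#' approximation is involved.
#'
#' Convergence is declared when the relative change of the parameter
#' vector falls below `tol`. On failure (non-convergence within `maxit`,
#' or a breakdown of the factorization) the returned object carries
#' `converged = FALSE`; callers running replicated simulations should
#' record the failure and discard the replicate.
#'
#' @param perf performance table (see [build_mme()]).
#' @param Ainv sparse inverse relationship matrix.
#' @param G_start,R_start starting values. The conventional choice is 0.9
#'   times the true (or best prior) genetic values and 1.1 times the
#'   residual values.
#' @param tol relative-change convergence criterion (default `1e-11`).
#' @param maxit maximum number of iterations.
#' @param verbose print the likelihood trace.
#' @return object of class `apisim_reml`: estimated `G` (over included
#'   effects) and `R` (over included traits), `converged`, `iterations`,
#'   `logLik` trace (restricted log-likelihood up to a constant), and the
#'   final [solve_blup()]-style solution.
#' @export
reml_estimate <- function(perf, Ainv, G_start, R_start, tol = 1e-11,
                          maxit = 100L, verbose = FALSE) {
  sys <- build_mme(perf, Ainv)
  G <- restrict_G(sys, G_start)
  R <- restrict_R(sys, R_start)
  k <- sys$k; kt <- length(sys$traits)
  gpairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  gpairs <- gpairs[order(gpairs[, 2L], gpairs[, 1L]), , drop = FALSE]
  rpairs <- which(upper.tri(matrix(0, kt, kt), diag = TRUE), arr.ind = TRUE)
  rpairs <- rpairs[order(rpairs[, 2L], rpairs[, 1L]), , drop = FALSE]
  n_gp <- nrow(gpairs); n_rp <- nrow(rpairs)
  theta <- c(G[cbind(gpairs[, 1L], gpairs[, 2L])],
             R[cbind(rpairs[, 1L], rpairs[, 2L])])
  unpack <- function(th) {
    Gm <- matrix(0, k, k)
    Gm[cbind(gpairs[, 1L], gpairs[, 2L])] <- th[seq_len(n_gp)]
    Gm[lower.tri(Gm)] <- t(Gm)[lower.tri(Gm)]
    Rm <- matrix(0, kt, kt)
    Rm[cbind(rpairs[, 1L], rpairs[, 2L])] <- th[n_gp + seq_len(n_rp)]
    Rm[lower.tri(Rm)] <- t(Rm)[lower.tri(Rm)]
    list(G = Gm, R = Rm)
  }
  is_pd <- function(M, floor = 1e-10) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    min(ev) > floor * max(abs(ev), 1e-12)
  }
  # project a symmetric matrix onto the (numerically) PD cone, as the
  # standard AI-REML programs do when an update crosses the boundary
  pd_project <- function(M, floor = 1e-6) {
    ei <- eigen(M, symmetric = TRUE)
    lo <- floor * max(abs(ei$values), 1e-12)
    if (min(ei$values) >= lo) return(M)
    v <- pmax(ei$values, lo)
    ei$vectors %*% (v * t(ei$vectors))
  }
  st <- reml_state(sys)
  Ch <- NULL
  logl_trace <- numeric(0)
  it <- 0L
  converged <- FALSE
  msg <- "ok"
  lambda <- 0           # Levenberg-Marquardt damping on the AI matrix
  best_ll <- -Inf
  theta_best <- theta
  q_best <- NULL
  reverts <- 0L
  # damped AI step via eigen pseudo-inverse (the AI matrix can be
  # rank-deficient on small or poorly connected data)
  ai_step <- function(AI, grad, lam, theta, theta_em) {
    ev <- eigen((AI + t(AI)) / 2, symmetric = TRUE)
    lmax <- max(ev$values, 1e-300)
    keep <- ev$values > 1e-8 * lmax
    if (!any(keep)) return(NULL)
    V <- ev$vectors[, keep, drop = FALSE]
    s <- drop(V %*% ((crossprod(V, grad)) / (ev$values[keep] + lam * lmax)))
    # flat directions (AI null space) move toward the EM fixed point
    if (any(!keep)) {
      dn <- theta_em - theta
      s <- s + dn - drop(V %*% crossprod(V, dn))
    }
    s
  }
  while (it < maxit) {
    it <- it + 1L
    q <- try(reml_iteration(sys, st, unpack(theta)$G, unpack(theta)$R, Ch),
             silent = TRUE)
    if (inherits(q, "try-error")) { msg <- as.character(q); break }
    Ch <- q$Ch
    logl_trace <- c(logl_trace, q$logl)
    if (verbose) {
      cat(sprintf("it %3d  logL %.8f  lambda %.1e\n", it, q$logl, lambda))
    }
    if (q$logl < best_ll - 1e-9 * max(1, abs(best_ll))) {
      # last step reduced the likelihood: revert and damp harder
      lambda <- if (lambda == 0) 1e-4 else lambda * 10
      theta <- theta_best
      q <- q_best
      reverts <- reverts + 1L
      if (reverts > 30L) { msg <- "step control failed"; break }
    } else {
      theta_best <- theta; q_best <- q; best_ll <- q$logl
      lambda <- lambda / 10
      if (lambda < 1e-12) lambda <- 0
    }
    theta_em <- c(q$G_em[cbind(gpairs[, 1L], gpairs[, 2L])],
                  q$R_em[cbind(rpairs[, 1L], rpairs[, 2L])])
    step_ok <- FALSE
    s <- ai_step(q$AI, q$grad, lambda, theta, theta_em)
    if (!is.null(s)) {
      cand <- theta + s
      pr <- unpack(cand)
      if (!is_pd(pr$G) || !is_pd(pr$R)) {
        # half-step first; if still outside, project onto the PD cone
        cand <- theta + 0.5 * s
        pr <- unpack(cand)
        if (!is_pd(pr$G) || !is_pd(pr$R)) {
          pr$G <- pd_project(pr$G); pr$R <- pd_project(pr$R)
          cand <- c(pr$G[cbind(gpairs[, 1L], gpairs[, 2L])],
                    pr$R[cbind(rpairs[, 1L], rpairs[, 2L])])
        }
      }
      theta_new <- cand
      step_ok <- TRUE
    }
    if (!step_ok) {
      theta_new <- theta_em
      pr <- unpack(theta_new)
      if (!is_pd(pr$G) || !is_pd(pr$R)) { msg <- "EM step left PD cone"; break }
    }
    # squared relative norm of the parameter change, as in the standard
    # AI-REML programs whose criterion this mirrors
    delta <- sum((theta_new - theta)^2) / max(sum(theta^2), 1e-300)
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  theta <- if (converged) theta else theta_best
  est <- unpack(theta)
  en <- bv_names()[sys$effects]; tn <- c("T1", "T2")[sys$traits]
  dimnames(est$G) <- list(en, en); dimnames(est$R) <- list(tn, tn)
  structure(list(G = est$G, R = est$R, converged = converged,
                 iterations = it, logLik = logl_trace, message = msg,
                 traits = sys$traits, effects = sys$effects,
                 n_records = sys$N),
            class = "apisim_reml")
}

#' @export
print.apisim_reml <- function(x, ...) {
  cat(sprintf("apisim_reml: %s after %d iterations (%d records)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$n_records))
  cat("genetic covariance:\n"); print(round(x$G, 4))
  cat("residual covariance:\n"); print(round(x$R, 4))
  invisible(x)
}

# ---- internal machinery -----------------------------------------------

# per-system constant index structures for trace extraction
reml_state <- function(sys) {
  st <- new.env(parent = emptyenv())
  st$template <- NULL     # pattern superset of C
  st$maps <- NULL         # lookup indices into the factor pattern
  st
}

# pattern superset: assemble C with strictly positive surrogate weights
pattern_template <- function(sys) {
  onesR <- matrix(1, 2, 2) + diag(2)        # any PD-ish full pattern
  onesG <- matrix(1, 4, 4) + diag(4)
  m <- mme_matrices(sys, onesG, onesR)
  m$C
}

# selected inverse of C = L L' on the pattern of L, with the trailing
# (nearly dense) block of the factor handled by dense inversion
selected_inverse <- function(L, work_budget = 2e7, max_dense = 3000L) {
  n <- nrow(L)
  cs <- diff(L@p)
  prefix <- c(0, cumsum(as.numeric(cs)^2))   # recursion work before col j
  jcut <- max(which(prefix <= work_budget))  # largest feasible cutoff
  jcut <- max(jcut, n - max_dense + 1L)
  if (n - jcut + 1L < 50L) jcut <- n + 1L    # not worth a dense block
  if (jcut > n) {
    zd <- matrix(0, 0, 0)
  } else {
    T_ <- jcut:n
    Ltt <- as.matrix(L[T_, T_, drop = FALSE])
    zd <- chol2inv(t(Ltt))
  }
  takahashi_cpp(L@p, L@i, L@x, n, jcut, zd)
}

# sorted-key lookup structure over the factor pattern; built once per fit
selinv_index <- function(Ch, L) {
  n <- L@Dim[1]
  keys_col <- rep.int(seq_along(diff(L@p)), diff(L@p))
  key_all <- (keys_col - 1) * (n + 1) + L@i + 1
  ord <- order(key_all)
  list(iperm = order(Ch@perm + 1L),   # original -> permuted position
       sorted = key_all[ord], ord = ord, n = n)
}

# positions of entries (I, J) (original indices) inside the lower factor
# pattern values vector
selinv_map <- function(lk, I, J) {
  pi_ <- lk$iperm[I]; pj <- lk$iperm[J]
  lo <- pmin(pi_, pj); hi <- pmax(pi_, pj)
  key_need <- (lo - 1) * (lk$n + 1) + hi
  pos <- findInterval(key_need, lk$sorted)
  hit <- pos >= 1L & lk$sorted[pmax(pos, 1L)] == key_need
  out <- rep(NA_integer_, length(key_need))
  out[hit] <- lk$ord[pos[hit]]
  out
}

# one REML iteration's worth of quantities at (G, R)
reml_iteration <- function(sys, st, G, R, Ch = NULL) {
  k <- sys$k; kt <- length(sys$traits)
  n_fix <- sys$n_fix; n_A <- sys$n_A
  Ginv <- solve(G)
  Rb <- R; RIb <- solve(Rb)
  m <- mme_matrices(sys, G, R)
  if (is.null(st$template)) st$template <- pattern_template(sys)
  C <- m$C + 0 * st$template
  if (is.null(Ch)) {
    Ch <- Matrix::Cholesky(C, LDL = FALSE, super = FALSE, perm = TRUE)
  } else {
    Ch <- Matrix::update(Ch, C)
  }
  L <- as(Ch, "sparseMatrix")
  sol <- as.numeric(Matrix::solve(Ch, m$rhs))
  ySiy <- sum(as.numeric(m$Si %*% sys$y) * sys$y)
  yPy <- ySiy - sum(sol * as.numeric(m$rhs))
  # residual log-determinant over colonies
  ldR <- 0
  if (nrow(sys$r_both)) ldR <- ldR + nrow(sys$r_both) * determinant(Rb)$modulus
  if (nrow(sys$r_single)) {
    tloc <- match(sys$r_single$trait, sys$traits)
    ldR <- ldR + sum(log(diag(Rb))[tloc])
  }
  ldC <- 2 * sum(log(Matrix::diag(L)))
  ldG <- n_A * determinant(G)$modulus
  logl <- -0.5 * (as.numeric(ldR) + as.numeric(ldG) + ldC + yPy)
  # selected inverse of C on the factor pattern
  Zx <- selected_inverse(L)
  # ---- index maps (constant across iterations) ----
  if (is.null(st$maps)) st$maps <- build_maps(sys, Ch, L)
  mp <- st$maps
  # ---- genetic blocks ----
  u <- sol[(n_fix + 1L):sys$p]
  Umat <- matrix(u, nrow = n_A, ncol = k, byrow = TRUE)
  AiU <- as.matrix(sys$Ainv %*% Umat)
  UAU <- crossprod(Umat, AiU)                       # k x k
  Sstack <- matrix(Zx[mp$g_pos], nrow = length(mp$g_ax), ncol = k * k)
  if (anyNA(Sstack)) stop("selected-inverse lookup failed (genetic block)")
  Tquad <- colSums(mp$g_ax * (Sstack %*% (Ginv %x% Ginv)))  # vec(G^-1 S G^-1) sums
  Tem <- colSums(mp$g_ax * Sstack)                          # vec(S) sums
  G_em <- (UAU + matrix(Tem, k, k)) / n_A
  # gradient / AI ingredients
  Py <- as.numeric(m$Si %*% (sys$y - as.numeric(sys$W %*% sol)))
  s_vec <- as.numeric(Matrix::crossprod(sys$W, Py))[(n_fix + 1L):sys$p]
  Smat <- matrix(s_vec, nrow = n_A, ncol = k, byrow = TRUE)  # Z'Py per node
  Vmat <- Umat %*% Ginv                                      # G^-1 u per node
  SV <- crossprod(Smat, Vmat)                                # k x k
  gpairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  gpairs <- gpairs[order(gpairs[, 2L], gpairs[, 1L]), , drop = FALSE]
  TquadM <- matrix(Tquad, k, k)
  grad_g <- numeric(nrow(gpairs))
  Fg <- matrix(0, sys$N, nrow(gpairs))
  for (pidx in seq_len(nrow(gpairs))) {
    e <- gpairs[pidx, 1L]; f <- gpairs[pidx, 2L]
    if (e == f) {
      trPV <- n_A * Ginv[e, e] - TquadM[e, e]
      quad <- SV[e, e]
      vtil <- outer(Vmat[, e], as.numeric(seq_len(k) == e))
    } else {
      trPV <- 2 * n_A * Ginv[e, f] - (TquadM[e, f] + TquadM[f, e])
      quad <- SV[e, f] + SV[f, e]
      vtil <- outer(Vmat[, f], as.numeric(seq_len(k) == e)) +
              outer(Vmat[, e], as.numeric(seq_len(k) == f))
    }
    grad_g[pidx] <- -0.5 * (trPV - quad)
    # f_k = Z vtil: pick the (node, effect) entries hit by each observation
    Fg[, pidx] <- vtil[cbind(sys$obs$wg, match(2L * sys$obs$trait - 1L, sys$effects))] +
                  vtil[cbind(sys$obs$queen, match(2L * sys$obs$trait, sys$effects))]
  }
  # ---- residual blocks ----
  # block sums of the selected inverse over each colony's equation columns
  zb <- residual_block_sums(sys, mp, Zx)
  ehat <- sys$y - as.numeric(sys$W %*% sol)
  rpairs <- which(upper.tri(matrix(0, kt, kt), diag = TRUE), arr.ind = TRUE)
  rpairs <- rpairs[order(rpairs[, 2L], rpairs[, 1L]), , drop = FALSE]
  grad_r <- numeric(nrow(rpairs))
  Fr <- matrix(0, sys$N, nrow(rpairs))
  R_em <- matrix(0, kt, kt)
  nb <- nrow(sys$r_both)
  # EM for R
  if (kt == 2L) {
    N11 <- nb + sum(sys$r_single$trait == sys$traits[1L])
    N22 <- nb + sum(sys$r_single$trait == sys$traits[2L])
    e1b <- if (nb) ehat[sys$r_both[, 1L]] else numeric(0)
    e2b <- if (nb) ehat[sys$r_both[, 2L]] else numeric(0)
    s1 <- sys$r_single$row[sys$r_single$trait == sys$traits[1L]]
    s2 <- sys$r_single$row[sys$r_single$trait == sys$traits[2L]]
    R_em[1, 1] <- (sum(e1b^2) + sum(ehat[s1]^2) + zb$d11) / N11
    R_em[2, 2] <- (sum(e2b^2) + sum(ehat[s2]^2) + zb$d22) / N22
    if (nb) R_em[1, 2] <- R_em[2, 1] <- (sum(e1b * e2b) + zb$d12) / nb
  } else {
    Nt <- sys$N
    R_em[1, 1] <- (sum(ehat^2) + zb$d11) / Nt
  }
  for (pidx in seq_len(nrow(rpairs))) {
    s <- rpairs[pidx, 1L]; t <- rpairs[pidx, 2L]
    Edot <- matrix(0, kt, kt); Edot[s, t] <- Edot[t, s] <- 1
    Q <- RIb %*% Edot %*% RIb
    # tr(Sigma^-1 Rdot)
    tr1 <- 0
    if (nb) tr1 <- tr1 + nb * sum(RIb * Edot)
    if (nrow(sys$r_single)) {
      tloc <- match(sys$r_single$trait, sys$traits)
      if (s == t) tr1 <- tr1 + sum(1 / diag(Rb)[tloc] * (tloc == s))
    }
    # tr(C^-1 W' Si Rdot Si W) via per-colony block sums
    tr2 <- 0
    if (nb) {
      tr2 <- tr2 + Q[1, 1] * zb$d11b + Q[2, 2] * zb$d22b + 2 * Q[1, 2] * zb$d12b
    }
    if (nrow(sys$r_single) && s == t) {
      tloc <- match(sys$r_single$trait, sys$traits)
      sel <- tloc == s
      if (any(sel)) {
        tr2 <- tr2 + sum((1 / diag(Rb)[tloc][sel])^2 * zb$single[sel])
      }
    }
    # quadratic and AI column
    quad <- 0
    fcol <- numeric(sys$N)
    if (nb) {
      p1 <- Py[sys$r_both[, 1L]]; p2 <- Py[sys$r_both[, 2L]]
      if (s == t) {
        quad <- quad + sum((if (s == 1) p1 else p2)^2)
        fcol[sys$r_both[, s]] <- if (s == 1) p1 else p2
      } else {
        quad <- quad + 2 * sum(p1 * p2)
        fcol[sys$r_both[, 1L]] <- p2
        fcol[sys$r_both[, 2L]] <- p1
      }
    }
    if (nrow(sys$r_single) && s == t) {
      tloc <- match(sys$r_single$trait, sys$traits)
      sel <- sys$r_single$row[tloc == s]
      quad <- quad + sum(Py[sel]^2)
      fcol[sel] <- Py[sel]
    }
    grad_r[pidx] <- -0.5 * (tr1 - tr2 - quad)
    Fr[, pidx] <- fcol
  }
  # ---- average information ----
  Fall <- cbind(Fg, Fr)
  SiF <- m$Si %*% Fall
  WtSiF <- Matrix::crossprod(sys$W, SiF)
  CiWtSiF <- Matrix::solve(Ch, WtSiF)
  PF <- SiF - m$Si %*% (sys$W %*% CiWtSiF)
  AI <- 0.5 * as.matrix(Matrix::crossprod(Fall, PF))
  list(Ch = Ch, logl = logl, grad = c(grad_g, grad_r), AI = AI,
       G_em = G_em, R_em = R_em, sol = sol)
}

# lookup maps from original C coordinates into the factor pattern
build_maps <- function(sys, Ch, L) {
  k <- sys$k; n_fix <- sys$n_fix
  lk <- selinv_index(Ch, L)
  Tr <- as(sys$Ainv, "TsparseMatrix")
  ai <- Tr@i + 1L; aj <- Tr@j + 1L; ax <- Tr@x
  off <- ai != aj
  ai2 <- c(ai, aj[off]); aj2 <- c(aj, ai[off]); ax2 <- c(ax, ax[off])
  eg <- expand.grid(e = seq_len(k), f = seq_len(k))
  I <- rep((ai2 - 1L) * k, each = k * k) + n_fix + eg$e
  J <- rep((aj2 - 1L) * k, each = k * k) + n_fix + eg$f
  g_pos <- matrix(selinv_map(lk, I, J), nrow = length(ax2), ncol = k * k,
                  byrow = TRUE)
  # per-colony equation columns
  nb <- nrow(sys$r_both)
  both_cols <- NULL
  if (nb) {
    r1 <- sys$r_both[, 1L]; r2 <- sys$r_both[, 2L]
    both_cols <- list(
      c1 = cbind(if (sys$use_fixed) sys$fix_col[r1] else NULL,
                 sys$colW[r1], sys$colQ[r1]),
      c2 = cbind(if (sys$use_fixed) sys$fix_col[r2] else NULL,
                 sys$colW[r2], sys$colQ[r2]))
  }
  single_cols <- NULL
  if (nrow(sys$r_single)) {
    rs <- sys$r_single$row
    single_cols <- cbind(if (sys$use_fixed) sys$fix_col[rs] else NULL,
                         sys$colW[rs], sys$colQ[rs])
  }
  pairmap <- function(Ca, Cb) {
    na <- ncol(Ca)
    out <- vector("list", na * ncol(Cb))
    idx <- 0L
    for (a in seq_len(na)) for (b in seq_len(ncol(Cb))) {
      idx <- idx + 1L
      out[[idx]] <- selinv_map(lk, Ca[, a], Cb[, b])
    }
    out
  }
  maps <- list(g_pos = g_pos, g_ax = ax2)
  if (nb) {
    maps$b11 <- pairmap(both_cols$c1, both_cols$c1)
    maps$b22 <- pairmap(both_cols$c2, both_cols$c2)
    maps$b12 <- pairmap(both_cols$c1, both_cols$c2)
  }
  if (!is.null(single_cols)) maps$ss <- pairmap(single_cols, single_cols)
  maps
}

# per-colony sums of selected-inverse entries over equation-column pairs
residual_block_sums <- function(sys, mp, Zx) {
  total <- function(lst) {
    if (is.null(lst)) return(list(sum = 0, per = numeric(0)))
    per <- 0
    for (v in lst) per <- per + Zx[v]
    list(sum = sum(per), per = per)
  }
  b11 <- total(mp$b11); b22 <- total(mp$b22); b12 <- total(mp$b12)
  ss <- total(mp$ss)
  # d11: trace-correction sums for EM (both + singles of trait 1 handled
  # by caller splitting); here: d11 = sum over trait-1 rows of colonies
  nb <- nrow(sys$r_both)
  d11 <- b11$sum; d22 <- b22$sum; d12 <- b12$sum
  if (length(ss$per)) {
    tloc <- match(sys$r_single$trait, sys$traits)
    d11 <- d11 + sum(ss$per[tloc == 1L])
    d22 <- d22 + sum(ss$per[tloc == 2L])
  }
  list(d11 = d11, d22 = d22, d12 = d12,
       d11b = b11$sum, d22b = b22$sum, d12b = b12$sum,
       single = ss$per)
}
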