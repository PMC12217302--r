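#' Mixed-model equations for the two-trait colony model
#'
#' Builds the Henderson system for colony records
#' `y = apiary-by-year + worker effect (worker group) + queen effect
#' (queen) + residual`, with the genetic effects of all pedigree nodes
#' jointly distributed as `N(0, A x G)` (Kronecker) and per-colony
#' residual covariance `R` across recorded traits. Missing traits are
#' handled by per-trait incidence (no imputation).
#'
#' The returned object holds everything that does not depend on the
#' variance parameters (incidence matrices, colony grouping, index maps),
#' so that REML can re-weight the system cheaply at each iterate.
#'
#' @param perf performance table: data.frame with columns `queen`,
#'   `worker_group` (pedigree node ids), `apiary`, `year`, `y_T1`, `y_T2`
#'   (NA = missing).
#' @param Ainv sparse inverse relationship matrix covering all node ids
#'   appearing in `perf`.
#' @param traits traits to include (default: those with any record).
#' @param use_fixed include apiary-by-year-by-trait fixed effects
#'   (default TRUE; FALSE fits a mean-zero model, used in closed-form
#'   checks).
#' @return an object of class `mme_system`.
#' @export
build_mme <- function(perf, Ainv, traits = NULL, use_fixed = TRUE) {
  perf <- as.data.frame(perf)
  n_A <- nrow(Ainv)
  ycols <- c("y_T1", "y_T2")
  if (is.null(traits)) {
    traits <- which(vapply(ycols, function(cl) any(!is.na(perf[[cl]])), TRUE))
  }
  traits <- sort(as.integer(traits))
  k_t <- length(traits)
  if (k_t == 0L) stop("no phenotypes")
  # one genetic effect pair (W, Q) per included trait
  effects <- as.integer(unlist(lapply(traits, function(t) c(2L * t - 1L, 2L * t))))
  k <- length(effects)
  eff_pos <- function(eff) match(eff, effects)
  # observations: colony x trait long format
  obs <- do.call(rbind, lapply(traits, function(t) {
    keep <- !is.na(perf[[ycols[t]]])
    if (!any(keep)) return(NULL)
    data.frame(colony = which(keep), trait = t, y = perf[[ycols[t]]][keep],
               queen = perf$queen[keep], wg = perf$worker_group[keep],
               apiary = perf$apiary[keep], year = perf$year[keep])
  }))
  obs <- obs[order(obs$colony, obs$trait), ]
  N <- nrow(obs)
  if (any(obs$queen > n_A | obs$wg > n_A)) {
    stop("performance file references nodes outside the relationship matrix")
  }
  # fixed part
  if (use_fixed) {
    flev <- factor(paste(obs$apiary, obs$year, obs$trait, sep = ":"))
    n_fix <- nlevels(flev)
    fix_col <- as.integer(flev)
  } else {
    n_fix <- 0L
    fix_col <- integer(N)
    flev <- factor(character(N))
  }
  # random columns: node-major blocks of size k
  col_of <- function(node, eff) n_fix + (node - 1L) * k + eff_pos(eff)
  colW <- col_of(obs$wg, 2L * obs$trait - 1L)
  colQ <- col_of(obs$queen, 2L * obs$trait)
  p <- n_fix + n_A * k
  ii <- c(if (use_fixed) seq_len(N), seq_len(N), seq_len(N))
  jj <- c(if (use_fixed) fix_col, colW, colQ)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, p))
  # colony classes: indices of obs rows per colony
  split_rows <- split(seq_len(N), obs$colony)
  n_per <- lengths(split_rows)
  both <- split_rows[n_per == 2L]
  r_both <- if (length(both)) matrix(unlist(both), ncol = 2L, byrow = TRUE) else
    matrix(integer(), ncol = 2L)
  singles <- unlist(split_rows[n_per == 1L], use.names = FALSE)
  r_single <- data.frame(row = singles, trait = obs$trait[singles])
  structure(list(
    obs = obs, y = obs$y, W = W, N = N, p = p, n_fix = n_fix, n_A = n_A,
    k = k, traits = traits, effects = effects, fix_levels = levels(flev),
    fix_col = fix_col, colW = colW, colQ = colQ,
    r_both = r_both, r_single = r_single,
    Ainv = Matrix::forceSymmetric(Ainv), use_fixed = use_fixed
  ), class = "mme_system")
}

#' @export
print.mme_system <- function(x, ...) {
  cat(sprintf(
    "mme_system: %d records (%d colonies both traits, %d single), %d fixed levels,\n  %d pedigree nodes x %d genetic effects\n",
    x$N, nrow(x$r_both), nrow(x$r_single), x$n_fix, x$n_A, x$k))
  invisible(x)
}

# residual covariance restricted to the included traits
restrict_R <- function(sys, R) {
  R <- as.matrix(R)
  if (all(dim(R) == c(2L, 2L)) && length(sys$traits) < 2L) {
    R <- R[sys$traits, sys$traits, drop = FALSE]
  }
  R
}

# genetic covariance restricted to the included effects
restrict_G <- function(sys, G) {
  G <- as.matrix(G)
  if (all(dim(G) == c(4L, 4L)) && sys$k < 4L) {
    G <- G[sys$effects, sys$effects, drop = FALSE]
  }
  G
}

# sparse block-diagonal inverse residual covariance over observations;
# explicit zeros are kept so the sparsity pattern is invariant in R
sigma_inv <- function(sys, R) {
  R <- restrict_R(sys, R)
  ii <- jj <- integer(0); xx <- numeric(0)
  if (nrow(sys$r_both)) {
    RI <- solve(R)
    r1 <- sys$r_both[, 1L]; r2 <- sys$r_both[, 2L]
    ii <- c(r1, r2, r1, r2)
    jj <- c(r1, r2, r2, r1)
    xx <- c(rep(RI[1, 1], length(r1)), rep(RI[2, 2], length(r1)),
            rep(RI[1, 2], length(r1)), rep(RI[2, 1], length(r1)))
  }
  if (nrow(sys$r_single)) {
    tloc <- match(sys$r_single$trait, sys$traits)
    ii <- c(ii, sys$r_single$row); jj <- c(jj, sys$r_single$row)
    xx <- c(xx, 1 / diag(R)[tloc])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(sys$N, sys$N))
}

# A^-1 (x) G^-1 expanded over node-major blocks, keeping all k^2 entries
# per pedigree pattern entry (pattern-stable across REML iterates)
g_side <- function(sys, G) {
  Ginv <- solve(restrict_G(sys, G))
  k <- sys$k
  Tr <- as(sys$Ainv, "TsparseMatrix")
  ai <- Tr@i + 1L; aj <- Tr@j + 1L; ax <- Tr@x
  # symmetric storage keeps only one triangle; expand
  off <- ai != aj
  ai <- c(ai, aj[off]); aj2 <- c(aj, Tr@i[off] + 1L); ax <- c(ax, Tr@x[off])
  nz <- length(ai)
  eg <- expand.grid(e = seq_len(k), f = seq_len(k))
  ii <- rep((ai - 1L) * k, each = k * k) + sys$n_fix + eg$e
  jj <- rep((aj2 - 1L) * k, each = k * k) + sys$n_fix + eg$f
  xx <- rep(ax, each = k * k) * as.numeric(Ginv)[ (eg$f - 1L) * k + eg$e ]
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(sys$p, sys$p))
}

# full coefficient matrix and right-hand side for given (G, R)
mme_matrices <- function(sys, G, R) {
  Si <- sigma_inv(sys, R)
  WtSi <- Matrix::crossprod(sys$W, Si)
  C <- WtSi %*% sys$W + g_side(sys, G)
  rhs <- WtSi %*% sys$y
  list(C = Matrix::forceSymmetric(C), rhs = rhs, Si = Si)
}

#' Solve the BLUP equations
#'
#' Assembles and solves the mixed-model equations at known variance
#' components, returning fixed-effect solutions and EBVs for every
#' pedigree node.
#'
#' @param sys an [build_mme()] system.
#' @param G genetic covariance (4x4, or matching the system's effects).
#' @param R residual covariance (2x2, or matching the system's traits).
#' @return list of class `blup_fit`: `ebv` (nodes x effects matrix with
#'   columns named after the effects), `fixed` (named vector), `sol` (full
#'   solution), and the residual norm of the solved system.
#' @export
solve_blup <- function(sys, G, R) {
  m <- mme_matrices(sys, G, R)
  Ch <- Matrix::Cholesky(m$C, LDL = FALSE, super = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(Ch, m$rhs))
  resid <- as.numeric(m$C %*% sol - m$rhs)
  scale <- max(1, sqrt(sum(as.numeric(m$rhs)^2)))
  ebv <- matrix(sol[(sys$n_fix + 1L):sys$p], nrow = sys$n_A, ncol = sys$k,
                byrow = TRUE)
  colnames(ebv) <- bv_names()[sys$effects]
  fixed <- if (sys$n_fix) stats::setNames(sol[seq_len(sys$n_fix)], sys$fix_levels)
           else numeric(0)
  structure(list(ebv = ebv, fixed = fixed, sol = sol,
                 resid_norm = sqrt(sum(resid^2)) / scale),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("blup_fit: %d nodes x %d effects, %d fixed levels (rel. residual %.2e)\n",
              nrow(x$ebv), ncol(x$ebv), length(x$fixed), x$resid_norm))
  invisible(x)
}

#' Selection index from EBVs
#'
#' Combines worker and queen EBVs per trait by summation, then applies the
#' breeding-goal weights. Dams are ranked on the index of their worker
#' group (their offspring's expected value, since breeding queens are
#' mated before selection); sires on their own index.
#'
#' @param ebv node x effect EBV matrix from [solve_blup()] (columns among
#'   `W1, Q1, W2, Q2`), or a full 4-column true-BV matrix.
#' @param nodes node ids to score (worker-group ids for the dam role, own
#'   queen ids for the sire role).
#' @param weights length-2 breeding-goal weights `(w1, w2)` on the early
#'   and late trait. Off-grid weights are allowed with a warning.
#' @return numeric index values aligned with `nodes`; ties in subsequent
#'   ranking should be broken by node id (use [order()] on `(-index,
#'   nodes)`).
#' @export
selection_index <- function(ebv, nodes, weights) {
  stopifnot(length(weights) == 2L)
  grid <- list(c(1, 0), c(0.75, 0.25), c(0.5, 0.5), c(0.25, 0.75), c(0, 1))
  if (!any(vapply(grid, function(g) isTRUE(all.equal(g, as.numeric(weights))), TRUE))) {
    warning("breeding-goal weights are off the 5-point grid")
  }
  idx <- numeric(length(nodes))
  for (t in 1:2) {
    if (weights[t] == 0) next
    wn <- bv_names()[2L * t - 1L]; qn <- bv_names()[2L * t]
    if (!(wn %in% colnames(ebv)) || !(qn %in% colnames(ebv))) {
      stop("EBVs for trait ", t, " are required by the weights but absent")
    }
    idx <- idx + weights[t] * (ebv[nodes, wn] + ebv[nodes, qn])
  }
  unname(idx)
}

#' Accuracy of a selection index
#'
#' Pearson correlation between true and estimated index over a candidate
#' cohort; undefined (NA) when either side has zero variance.
#'
#' @param true_index,estimated_index numeric vectors over the same
#'   candidates.
#' @return correlation coefficient or NA.
#' @export
index_accuracy <- function(true_index, estimated_index) {
  stopifnot(length(true_index) == length(estimated_index))
  if (length(true_index) < 2L) stop("need at least two candidates")
  if (stats::sd(true_index) == 0 || stats::sd(estimated_index) == 0) {
    return(NA_real_)
  }
  stats::cor(true_index, estimated_index)
}
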