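#' Gene-dropping estimate of the relationship matrix
#'
#' Independent Monte-Carlo validation of [compute_A()]: neutral allele
#' identities are dropped through the pedigree's generative model and
#' identity-by-descent sharing is scored directly.
#'
#' Each queen carries two allele ids (maternal: a random allele of her dam;
#' paternal: a random gamete of her sire — a random allele of the DPQ for
#' single-DPQ matings, or a random pool allele for open matings). A worker
#' group is the infinite-worker average: half a genome from its queen
#' (weights 0.5 on each queen allele) plus the equal-share mean of
#' `n_drones` father drones drawn once per mating (weights `1/n_drones`).
#' A pseudo-sire is the pool average of its `n_dummy_dpq` dummy DPQs'
#' gametes (uniform weights over the pool's alleles).
#'
#' With genome-content weight vectors \eqn{w_X} over founder alleles, the
#' additive relationship is estimated as
#' \eqn{\hat A(X,Y) = 0.5\, \mathrm{E}[\sum_{ij} w_{Xi} w_{Yj}
#' \mathbf{1}(a_i = a_j)]}, and \eqn{\hat F} as the probability that a
#' queen's two alleles are identical by descent.
#'
#' @param ped a [bee_pedigree()].
#' @param ids node ids to include (default: all; keep pedigrees small).
#' @param n_rep Monte-Carlo replicates.
#' @return list with matrices `A_hat` and `A_se` (standard errors of the
#'   per-replicate mean), and vectors `F_hat`, `F_se` for queen nodes.
#' @export
gene_drop_A <- function(ped, ids = NULL, n_rep = 20000L) {
  n <- ped$n
  if (is.null(ids)) ids <- seq_len(n)
  nd <- ped$n_drones
  nD <- ped$n_dummy_dpq
  # per node: integer allele matrix (n_rep x k), weights (k), and for
  # pseudo-sires an id range with uniform weights handled analytically
  alleles <- vector("list", n)
  weights <- vector("list", n)
  pool_range <- vector("list", n)   # c(lo, hi) for pseudo-sires
  next_id <- 1L
  pick2 <- function(M) {            # one random allele per rep from 2 cols
    sel <- stats::runif(n_rep) < 0.5
    ifelse(sel, M[, 1L], M[, 2L])
  }
  for (i in seq_len(n)) {
    k <- ped$kind[i]; dam <- ped$dam[i]; sire <- ped$sire[i]
    if (k == KIND_PSEUDO_SIRE) {
      pool_range[[i]] <- c(next_id, next_id + 2L * nD - 1L)
      next_id <- next_id + 2L * nD
    } else if (k == KIND_QUEEN && dam == 0L) {
      alleles[[i]] <- matrix(c(next_id, next_id + 1L), n_rep, 2L, byrow = TRUE)
      weights[[i]] <- c(1, 1)
      next_id <- next_id + 2L
    } else if (k == KIND_QUEEN) {
      mat <- pick2(alleles[[dam]])
      pat <- if (ped$kind[sire] == KIND_QUEEN) {
        pick2(alleles[[sire]])
      } else {
        r <- pool_range[[sire]]
        r[1L] + sample.int(r[2L] - r[1L] + 1L, n_rep, replace = TRUE) - 1L
      }
      alleles[[i]] <- cbind(mat, pat, deparse.level = 0)
      weights[[i]] <- c(1, 1)
    } else {                        # worker group
      drone_cols <- matrix(0L, n_rep, nd)
      for (dcol in seq_len(nd)) {
        drone_cols[, dcol] <- if (ped$kind[sire] == KIND_QUEEN) {
          pick2(alleles[[sire]])
        } else {
          r <- pool_range[[sire]]
          r[1L] + sample.int(r[2L] - r[1L] + 1L, n_rep, replace = TRUE) - 1L
        }
      }
      alleles[[i]] <- cbind(alleles[[dam]], drone_cols, deparse.level = 0)
      weights[[i]] <- c(0.5, 0.5, rep(1 / nd, nd))
    }
  }
  m <- length(ids)
  A_hat <- matrix(NA_real_, m, m); A_se <- matrix(NA_real_, m, m)
  pair_stat <- function(x, y) {
    # per-replicate weighted IBD sharing between nodes x and y
    s <- numeric(n_rep)
    px <- pool_range[[x]]; py <- pool_range[[y]]
    if (!is.null(px) && !is.null(py)) {
      val <- if (px[1L] == py[1L]) 0.25 / nD else 0
      return(rep(val, n_rep))
    }
    if (!is.null(px) || !is.null(py)) {
      if (!is.null(py)) { tmp <- x; x <- y; y <- tmp; px <- py }
      AY <- alleles[[y]]; wY <- weights[[y]]
      for (j in seq_along(wY)) {
        s <- s + wY[j] / (2 * nD) * (AY[, j] >= px[1L] & AY[, j] <= px[2L])
      }
      return(0.5 * s)
    }
    AX <- alleles[[x]]; wX <- weights[[x]]
    AY <- alleles[[y]]; wY <- weights[[y]]
    if (x == y) {
      for (i2 in seq_along(wX)) for (j in seq_along(wY)) {
        s <- s + wX[i2] * wY[j] * (AX[, i2] == AY[, j])
      }
      return(0.5 * s)
    }
    for (i2 in seq_along(wX)) for (j in seq_along(wY)) {
      s <- s + wX[i2] * wY[j] * (AX[, i2] == AY[, j])
    }
    0.5 * s
  }
  for (a in seq_len(m)) for (b in a:m) {
    s <- pair_stat(ids[a], ids[b])
    A_hat[a, b] <- A_hat[b, a] <- mean(s)
    A_se[a, b] <- A_se[b, a] <- stats::sd(s) / sqrt(n_rep)
  }
  F_hat <- rep(NA_real_, m); F_se <- rep(NA_real_, m)
  for (a in seq_len(m)) {
    i <- ids[a]
    if (ped$kind[i] == KIND_QUEEN) {
      ib <- alleles[[i]][, 1L] == alleles[[i]][, 2L]
      F_hat[a] <- mean(ib); F_se[a] <- stats::sd(ib) / sqrt(n_rep)
    }
  }
  lab <- ped$label[ids]
  dimnames(A_hat) <- dimnames(A_se) <- list(lab, lab)
  list(A_hat = A_hat, A_se = A_se, F_hat = F_hat, F_se = F_se)
}
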