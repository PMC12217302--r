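#' Draw founder breeding values
#'
#' Founder queens are unrelated and non-inbred; their length-4 breeding
#' value vectors (worker-T1, queen-T1, worker-T2, queen-T2) are drawn
#' i.i.d. from N(0, G). Uses the current RNG stream.
#'
#' @param G 4x4 additive covariance matrix from [build_G()].
#' @param n number of founders.
#' @return `n` x 4 matrix of breeding values.
#' @export
draw_founder_bvs <- function(G, n) {
  stopifnot(n >= 1, all(dim(G) == c(4L, 4L)))
  rmvn(n, G)
}

#' Sample gametes of diploid parents
#'
#' A gamete carries half the parent's breeding value plus a Mendelian
#' sampling deviation with covariance `0.25 * (1 - F) * G`; inbreeding of
#' the parent shrinks the sampling variance linearly.
#'
#' @param parent_bv parent breeding values: length-4 vector or n x 4 matrix.
#' @param parent_F parent inbreeding coefficient(s) in \[0, 1\], recycled.
#' @param G 4x4 additive covariance matrix.
#' @return matrix of gametic values, one row per row of `parent_bv`
#'   (gametic values live on the half-genome scale).
#' @export
make_gamete <- function(parent_bv, parent_F, G) {
  bv <- rbind(parent_bv)
  n <- nrow(bv)
  F_ <- rep_len(parent_F, n)
  if (any(F_ < 0 | F_ > 1)) stop("inbreeding coefficients must lie in [0, 1]")
  dev <- rmvn(n, 0.25 * G) * sqrt(1 - F_)
  0.5 * bv + dev
}

#' Sample drones of a drone-producing queen
#'
#' Drones arise from unfertilized eggs: a drone *is* a single gametic value
#' of its mother and transmits that genome clonally to every daughter.
#' Contract identical to [make_gamete()] applied to the DPQ.
#'
#' @inheritParams make_gamete
#' @param dpq_bv,dpq_F breeding values and inbreeding of the mother DPQ(s).
#' @param n number of drones per DPQ row.
#' @return `n * nrow(dpq_bv)` x 4 matrix; rows grouped by DPQ.
#' @export
make_drone <- function(dpq_bv, dpq_F, G, n = 1L) {
  bv <- rbind(dpq_bv)
  idx <- rep(seq_len(nrow(bv)), each = n)
  make_gamete(bv[idx, , drop = FALSE], rep(rep_len(dpq_F, nrow(bv)), each = n), G)
}

#' Breeding value of an offspring queen
#'
#' An offspring queen receives a maternal gamete of her dam plus the full
#' genome of her father drone (haplodiploidy: the drone contributes its
#' whole single genome).
#'
#' @param dam_bv dam breeding values (length-4 vector or n x 4 matrix).
#' @param dam_F dam inbreeding coefficient(s).
#' @param father_drone gametic value row(s) of the father drone, matched by
#'   row to `dam_bv`.
#' @param G 4x4 additive covariance matrix.
#' @return matrix of offspring breeding values.
#' @export
make_offspring_queen <- function(dam_bv, dam_F, father_drone, G) {
  gam <- make_gamete(dam_bv, dam_F, G)
  drone <- rbind(father_drone)
  if (nrow(drone) != nrow(gam)) stop("dam and father drone rows must match")
  gam + drone
}

#' Mean breeding value of a colony's worker group
#'
#' The worker group is modelled as an infinitely large set of daughters of
#' the queen: maternal Mendelian deviations average out, and the paternal
#' contribution is the equal-share mean of the father drones the queen
#' mated (polyandry).
#'
#' @param queen_bv queen breeding values (length-4 vector).
#' @param queen_F queen inbreeding coefficient (unused under the
#'   infinite-worker approximation; kept for interface completeness).
#' @param father_drones matrix of the queen's father drones (one gametic
#'   value per row), `n_drones` rows.
#' @param n_drones required number of drones (polyandry check).
#' @return length-4 worker-group mean breeding value.
#' @export
worker_group_mean_bv <- function(queen_bv, queen_F = 0, father_drones,
                                 n_drones = 8L) {
  drones <- rbind(father_drones)
  if (nrow(drones) != n_drones) {
    stop("expected ", n_drones, " father drones, got ", nrow(drones))
  }
  0.5 * as.numeric(queen_bv) + colMeans(drones)
}

#' Generate colony phenotypes
#'
#' A colony phenotype for trait t is the sum of the queen effect of its
#' queen, the mean worker effect of its worker group, the apiary-by-year
#' environmental effect, and an independent residual:
#' `y = a_Q + mean(a_W) + E + eps`. Unrecorded traits are set missing.
#'
#' @param queen_bv n x 4 matrix of queen breeding values.
#' @param worker_mean_bv n x 4 matrix of worker-group mean breeding values.
#' @param apiary_effect n x 2 matrix of apiary-by-year effects (early,
#'   late), one row per colony; draw one value per apiary x year x trait.
#' @param params a [genetic_params()] object (residual variances).
#' @param traits_to_record integer subset of `c(1, 2)`.
#' @return n x 2 matrix of phenotypes with `NA` for unrecorded traits.
#' @export
colony_phenotype <- function(queen_bv, worker_mean_bv, apiary_effect, params,
                             traits_to_record = c(1L, 2L)) {
  qbv <- rbind(queen_bv); wbv <- rbind(worker_mean_bv)
  n <- nrow(qbv)
  stopifnot(nrow(wbv) == n, all(traits_to_record %in% 1:2))
  E <- rbind(apiary_effect)
  if (nrow(E) == 1L && n > 1L) E <- E[rep(1L, n), , drop = FALSE]
  y <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("y_T1", "y_T2")))
  for (t in traits_to_record) {
    eps <- stats::rnorm(n, 0, sqrt(params$sigma2_eps))
    y[, t] <- qbv[, bv_index("Q", t)] + wbv[, bv_index("W", t)] + E[, t] + eps
  }
  y
}

#' Sample drones from an open-mating pseudo-sire pool
#'
#' Open-mated queens receive drones from a pool of `n_dummy_dpq` unknown,
#' unrelated, non-inbred dummy DPQs whose breeding values are N(0, G).
#' Each drone picks its dam uniformly from the pool, so two drones of the
#' same pseudo-sire share a dam with probability `1 / n_dummy_dpq`.
#'
#' @param n_drones number of drones to draw.
#' @param G 4x4 additive covariance matrix.
#' @param n_dummy_dpq pool size.
#' @return `n_drones` x 4 matrix of gametic values.
#' @export
draw_base_drones <- function(n_drones, G, n_dummy_dpq = 100L) {
  dam_idx <- sample.int(n_dummy_dpq, n_drones, replace = TRUE)
  uniq <- unique(dam_idx)
  dam_bv <- rmvn(length(uniq), G)
  rows <- match(dam_idx, uniq)
  make_gamete(dam_bv[rows, , drop = FALSE], 0, G)
}
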