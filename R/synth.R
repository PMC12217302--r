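#' Simulate a colony dataset with known parameters
#'
#' Standalone generator for evaluation and variance-component studies:
#' a multi-generation random-mating population with the colony phenotype
#' model (queen effect + worker-group mean + apiary-by-year effect +
#' residual), single-DPQ inseminations with the configured polyandry, and
#' no selection. Returns the pedigree, the performance table, and the
#' true breeding values, so estimators can be checked against the truth.
#'
#' @param params a [genetic_params()] object.
#' @param n_dams breeding dams per generation.
#' @param daughters_per_dam phenotyped daughters per dam.
#' @param n_generations generations after the founders.
#' @param n_dpq drone-producing queens per generation.
#' @param colonies_per_apiary target apiary size for the fixed effect.
#' @param traits traits recorded on every colony (default both).
#' @param share_drones if TRUE, the daughters of one dam draw their
#'   father drones from the dam's stored mating of `n_drones` drones
#'   (the biological process, which adds super-sister covariance beyond
#'   the expected-relationship matrix); if FALSE (default) every
#'   daughter receives an independent gamete of the mate, matching the
#'   relationship model exactly - the right choice for estimator
#'   validation.
#' @return list with `ped` ([bee_pedigree()]), `perf` (performance
#'   data.frame), `bv` (true breeding values per node), and `G`, `R`.
#' @export
simulate_colony_data <- function(params = genetic_params(),
                                 n_dams = 25L, daughters_per_dam = 20L,
                                 n_generations = 4L, n_dpq = 25L,
                                 colonies_per_apiary = 36L,
                                 traits = c(1L, 2L), share_drones = FALSE) {
  G <- build_G(params); R <- build_R(params)
  ped <- bee_pedigree(n_drones = params$n_drones,
                      n_dummy_dpq = params$n_dummy_dpq)
  nd <- params$n_drones
  k <- daughters_per_dam
  founders <- ped_add_batch(ped, rep(KIND_QUEEN, n_dams + n_dpq),
                            rep(0L, n_dams + n_dpq), rep(0L, n_dams + n_dpq),
                            rep(0L, n_dams + n_dpq), rep(0, n_dams + n_dpq),
                            rep(0, n_dams + n_dpq), rep(0, n_dams + n_dpq),
                            rep(1, n_dams + n_dpq))
  bv <- matrix(NA_real_, 0, 4)
  grow <- function(n) {
    if (n > nrow(bv)) bv <<- rbind(bv, matrix(NA_real_, n - nrow(bv), 4))
  }
  grow(ped$n)
  bv[founders, ] <- draw_founder_bvs(G, n_dams + n_dpq)
  dams <- founders[seq_len(n_dams)]
  dpqs <- founders[n_dams + seq_len(n_dpq)]
  perf <- vector("list", n_generations)
  for (g in seq_len(n_generations)) {
    n_col <- n_dams * k
    # dams' matings: one DPQ per dam, 8 drones each
    mate_of <- sample(dpqs, n_dams, replace = TRUE)
    F_new <- 0.5 * ped_rel(ped, dams, mate_of)
    dam_rep <- rep(dams, each = k)
    mate_rep <- rep(mate_of, each = k)
    dd_q <- 0.25 * (1 - ped$F[dam_rep]) + 0.25 * (1 - ped$F[mate_rep])
    qs <- ped_add_batch(ped, rep(KIND_QUEEN, n_col), dam_rep, mate_rep,
                        rep(g, n_col), rep(F_new, each = k),
                        rep(0.5, n_col), rep(0.5, n_col), dd_q)
    grow(ped$n)
    # father drone per daughter
    if (share_drones) {
      drone_pool <- make_gamete(bv[rep(mate_of, each = nd), , drop = FALSE],
                                rep(ped$F[mate_of], each = nd), G)
      pick <- (rep(seq_len(n_dams), each = k) - 1L) * nd +
        sample.int(nd, n_col, replace = TRUE)
      pat <- drone_pool[pick, , drop = FALSE]
    } else {
      pat <- make_gamete(bv[mate_rep, , drop = FALSE], ped$F[mate_rep], G)
    }
    bv[qs, ] <- make_gamete(bv[dam_rep, , drop = FALSE], ped$F[dam_rep], G) +
      pat
    # each daughter's own colony: mated to a random DPQ
    m2 <- sample(dpqs, n_col, replace = TRUE)
    dd_w <- 0.25 * (1 - ped$F[m2]) / nd
    ws <- ped_add_batch(ped, rep(KIND_WORKER_GROUP, n_col), qs, m2,
                        rep(g, n_col), rep(NA_real_, n_col),
                        rep(0.5, n_col), rep(0.5, n_col), dd_w)
    grow(ped$n)
    own_drones <- make_gamete(bv[rep(m2, nd), , drop = FALSE],
                              rep(ped$F[m2], nd), G)
    pat_mean <- matrix(0, n_col, 4)
    for (j in seq_len(nd)) {
      pat_mean <- pat_mean + own_drones[(j - 1L) * n_col + seq_len(n_col), ,
                                        drop = FALSE] / nd
    }
    bv[ws, ] <- 0.5 * bv[qs, , drop = FALSE] + pat_mean
    # phenotypes with an apiary-by-year fixed effect
    n_ap <- max(1L, round(n_col / colonies_per_apiary))
    E <- rmvn(n_ap, diag(params$sigma2_apiary))
    ap_of <- rep_len(seq_len(n_ap), n_col)[sample.int(n_col)]
    y <- colony_phenotype(bv[qs, , drop = FALSE], bv[ws, , drop = FALSE],
                          E[ap_of, , drop = FALSE], params,
                          traits_to_record = traits)
    perf[[g]] <- data.frame(queen = qs, worker_group = ws,
                            apiary = (g - 1L) * 1000L + ap_of, year = g,
                            y_T1 = y[, 1], y_T2 = y[, 2])
    dams <- sample(qs, n_dams)
    dpqs <- sample(setdiff(qs, dams), n_dpq)
  }
  list(ped = ped, perf = do.call(rbind, perf), bv = bv, G = G, R = R)
}
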