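#' @title Population state of a running breeding-scheme simulation
#' @description Internal mutable state: the bee pedigree, true breeding
#' values, stored matings (8 father drones per mated queen), the
#' performance file, cohort bookkeeping and the event ledger. Created by
#' [run_initialization()] and advanced by [run_base()] / [run_alt()].
#' @name population_state
NULL

new_population_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$G <- build_G(cfg$params)
  st$R <- build_R(cfg$params)
  st$ped <- bee_pedigree(n_drones = cfg$params$n_drones,
                         n_dummy_dpq = cfg$params$n_dummy_dpq)
  st$bv <- matrix(NA_real_, 4096L, 4L)
  # father-drone gametes per mated queen, 8 contiguous rows per node id
  st$drone_mat <- matrix(NA_real_, 4096L * cfg$params$n_drones, 4L)
  st$mate <- integer(0)        # mate node per queen id
  st$apiary <- integer(0)      # test apiary per queen id
  st$phenotyped <- logical(0)
  st$wg_lookup <- integer(0)   # worker-group node per phenotyped queen
  st$perf <- list()            # accumulated performance rows
  st$apiary_E <- new.env(parent = emptyenv())
  st$cohorts <- list()         # per year: list(BQ = ids, DPQ = ids)
  st$born <- list()            # cohorts as born, untouched by mortality
  st$selected <- list()        # per selection year: list(dams, sires)
  st$ledger <- list(cohort = list(), eval = list(), apiary = list())
  st$accuracy <- list()        # per evaluation year: dam/sire accuracy
  st$reml <- list()            # per evaluation year: convergence info
  st$failed <- FALSE
  class(st) <- "population_state"
  st
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d pedigree nodes, %d performance rows, %d cohorts\n",
              x$ped$n, length(x$perf), length(x$cohorts)))
  invisible(x)
}

# deep copy so Base and Alt can diverge from a shared Initialization
clone_population <- function(st) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(st, all.names = TRUE)) {
    v <- st[[nm]]
    if (is.environment(v) && !inherits(v, "bee_pedigree")) {
      e2 <- new.env(parent = emptyenv())
      for (n2 in ls(v, all.names = TRUE)) e2[[n2]] <- v[[n2]]
      out[[nm]] <- e2
    } else if (inherits(v, "bee_pedigree")) {
      p2 <- new.env(parent = emptyenv())
      for (n2 in ls(v, all.names = TRUE)) p2[[n2]] <- v[[n2]]
      class(p2) <- "bee_pedigree"
      out[[nm]] <- p2
    } else {
      out[[nm]] <- v
    }
  }
  class(out) <- "population_state"
  out
}

bv_grow <- function(st, need) {
  if (need > nrow(st$bv)) {
    add <- matrix(NA_real_, max(need, 2L * nrow(st$bv)) - nrow(st$bv), 4L)
    st$bv <- rbind(st$bv, add)
  }
  nd <- st$cfg$params$n_drones
  if (need * nd > nrow(st$drone_mat)) {
    add <- matrix(NA_real_,
                  max(need * nd, 2L * nrow(st$drone_mat)) - nrow(st$drone_mat), 4L)
    st$drone_mat <- rbind(st$drone_mat, add)
  }
  invisible(st)
}

# father drones of one queen (nd x 4)
drones_of <- function(st, id) {
  nd <- st$cfg$params$n_drones
  st$drone_mat[(id - 1L) * nd + seq_len(nd), , drop = FALSE]
}

meta_grow <- function(st, need) {
  if (need > length(st$mate)) {
    n0 <- length(st$mate)
    length(st$mate) <- need; st$mate[(n0 + 1L):need] <- 0L
    length(st$apiary) <- need; st$apiary[(n0 + 1L):need] <- 0L
    length(st$phenotyped) <- need; st$phenotyped[(n0 + 1L):need] <- FALSE
    length(st$wg_lookup) <- need; st$wg_lookup[(n0 + 1L):need] <- 0L
  }
  invisible(st)
}

# apiary-by-year environmental effects, one draw per apiary x year x trait
apiary_effects <- function(st, year) {
  key <- as.character(year)
  if (is.null(st$apiary_E[[key]])) {
    sa <- st$cfg$params$sigma2_apiary
    st$apiary_E[[key]] <- cbind(
      stats::rnorm(st$cfg$n_apiaries, 0, sqrt(sa[1])),
      stats::rnorm(st$cfg$n_apiaries, 0, sqrt(sa[2])))
  }
  st$apiary_E[[key]]
}

# batch open mating: one pseudo-sire per queen, 8 base drones each
open_mate_batch <- function(st, ids) {
  if (!length(ids)) return(invisible(st))
  ped <- st$ped
  nd <- st$cfg$params$n_drones
  nD <- st$cfg$params$n_dummy_dpq
  ps <- ped_add_batch(ped, rep(KIND_PSEUDO_SIRE, length(ids)),
                      rep(0L, length(ids)), rep(0L, length(ids)),
                      rep(NA_integer_, length(ids)),
                      rep(NA_real_, length(ids)),
                      rep(0, length(ids)), rep(0, length(ids)),
                      rep(pseudo_sire_var(nD), length(ids)))
  meta_grow(st, ped$n)
  st$mate[ids] <- ps
  # dams inside a pool are private to that queen; sample dam labels per
  # queen, draw one BV per distinct (queen, dam), then gametes in bulk
  nq <- length(ids)
  dam_lab <- matrix(sample.int(nD, nq * nd, replace = TRUE), nq, nd)
  key <- rep(seq_len(nq), nd) * (nD + 1L) + as.integer(dam_lab)
  uk <- unique(key)
  dam_bv <- rmvn(length(uk), st$G)
  rows <- match(key, uk)
  drones <- make_gamete(dam_bv[rows, , drop = FALSE], 0, st$G)
  bv_grow(st, max(ids))
  tgt <- rep((ids - 1L) * nd, nd) + rep(seq_len(nd), each = nq)
  st$drone_mat[tgt, ] <- drones
  invisible(st)
}

# --- founders ----------------------------------------------------------

add_founders <- function(st) {
  cfg <- st$cfg
  nf <- cfg$n_founders
  ids <- integer(nf)
  bvs <- draw_founder_bvs(st$G, nf)
  for (i in seq_len(nf)) {
    ids[i] <- add_node(st$ped, "QUEEN", birth_year = 1L)
  }
  bv_grow(st, max(ids)); meta_grow(st, max(ids))
  st$bv[ids, ] <- bvs
  # open-mate every founder to her own pseudo-sire with 8 base drones
  open_mate_batch(st, ids)
  st$apiary[ids] <- rep_len(seq_len(cfg$n_apiaries), nf)
  st$cohorts[["1"]] <- list(BQ = ids, DPQ = integer(0))
  st$born[["1"]] <- st$cohorts[["1"]]
  ids
}

# --- cohort production -------------------------------------------------

# Dams produce offspring queens of both paths; the father drone of every
# offspring is sampled from the dam's stored mating. New BQs are
# immediately inseminated (sire pool given); new DPQs stay open-mated.
produce_cohort <- function(st, dam_ids, year, sire_pool) {
  cfg <- st$cfg
  ped <- st$ped
  npd <- cfg$offspring_per_dam
  n_new <- length(dam_ids) * npd
  out <- list()
  # inbreeding of offspring is shared per dam (one mate per dam)
  F_dam <- ped$F[dam_ids]
  mate_dam <- st$mate[dam_ids]
  stopifnot(all(mate_dam > 0L))
  Foff <- numeric(length(dam_ids))
  for (i in seq_along(dam_ids)) {
    m <- mate_dam[i]
    if (ped$kind[m] == KIND_QUEEN) {
      Foff[i] <- 0.5 * ped_rel(ped, dam_ids[i], m)
    } else {
      Foff[i] <- ped_rel(ped, dam_ids[i], m)
    }
  }
  for (role in c("BQ", "DPQ")) {
    dam_rep <- rep(dam_ids, each = npd)
    Fd_rep <- rep(F_dam, each = npd)
    # Mendelian gamete from the dam + one stored father drone
    gam <- make_gamete(st$bv[dam_rep, , drop = FALSE], Fd_rep, st$G)
    nd0 <- cfg$params$n_drones
    drow <- (dam_rep - 1L) * nd0 + sample.int(nd0, n_new, replace = TRUE)
    bvs <- gam + st$drone_mat[drow, , drop = FALSE]
    # pedigree rules for queen offspring
    msire <- rep(mate_dam, each = npd)
    open_sire <- ped$kind[msire] == KIND_PSEUDO_SIRE
    v_pool <- pseudo_sire_var(ped$n_dummy_dpq)
    c2 <- ifelse(open_sire, 1, 0.5)
    dd <- 0.25 * (1 - Fd_rep) +
      ifelse(open_sire, 0.5 - v_pool, 0.25 * (1 - ped$F[msire]))
    ids <- ped_add_batch(ped, rep(KIND_QUEEN, n_new), dam_rep, msire,
                         rep(as.integer(year), n_new),
                         rep(Foff, each = npd), rep(0.5, n_new), c2, dd)
    bv_grow(st, max(ids)); meta_grow(st, max(ids))
    st$bv[ids, ] <- bvs
    # apiary allocation before any mortality: sister groups split
    st$apiary[ids] <- allocate_apiaries(length(dam_ids), npd,
                                        cfg$n_apiaries,
                                        cfg$apiaries_per_group)
    out[[role]] <- ids
  }
  # mate the new BQs: balanced random assignment to the sire pool
  bq <- out$BQ
  if (length(sire_pool)) {
    assigned <- mate_cohort(length(bq), sire_pool)
    st$mate[bq] <- assigned
    nd <- cfg$params$n_drones
    nq <- length(bq)
    rows <- rep(assigned, nd)            # queen-major stripes
    drones <- make_gamete(st$bv[rows, , drop = FALSE], ped$F[rows], st$G)
    bv_grow(st, max(bq))
    tgt <- rep((bq - 1L) * nd, nd) + rep(seq_len(nd), each = nq)
    st$drone_mat[tgt, ] <- drones
  }
  st$cohorts[[as.character(year)]] <- out
  st$born[[as.character(year)]] <- out
  st$ledger$cohort[[length(st$ledger$cohort) + 1L]] <-
    data.frame(year = year, born_per_path = n_new)
  out
}

# exact-fraction first mortality on both paths of a cohort
first_mortality <- function(st, year) {
  co <- st$cohorts[[as.character(year)]]
  co$BQ <- apply_mortality(co$BQ, st$cfg$mortality_rate)
  if (length(co$DPQ)) co$DPQ <- apply_mortality(co$DPQ, st$cfg$mortality_rate)
  st$cohorts[[as.character(year)]] <- co
  co
}

second_mortality <- function(st, year, roles = c("BQ", "DPQ")) {
  co <- st$cohorts[[as.character(year)]]
  for (r in roles) {
    if (length(co[[r]])) co[[r]] <- apply_mortality(co[[r]], st$cfg$mortality_rate)
  }
  st$cohorts[[as.character(year)]] <- co
  co
}

# --- phenotyping -------------------------------------------------------

# Phenotype the surviving colonies of the cohort born in `birth_year`
# during test year `birth_year + 1`. DPQs are open-mated at this point
# (own pseudo-sire + base drones). `traits_bq` / `traits_dpq` control the
# recorded traits; `avail` gives the year from which each trait's records
# enter the performance file.
phenotype_cohort <- function(st, birth_year,
                             traits_bq = c(1L, 2L), traits_dpq = c(1L, 2L),
                             avail_bq = NULL, avail_dpq = NULL) {
  cfg <- st$cfg
  ped <- st$ped
  test_year <- birth_year + 1L
  co <- st$cohorts[[as.character(birth_year)]]
  E <- apiary_effects(st, test_year)
  ap_counts <- integer(cfg$n_apiaries)
  for (role in c("BQ", "DPQ")) {
    ids <- co[[role]]
    if (!length(ids)) next
    traits <- if (role == "BQ") traits_bq else traits_dpq
    avail <- if (role == "BQ") avail_bq else avail_dpq
    if (is.null(avail)) {
      avail <- ifelse(traits == 1L, test_year, test_year + 1L)
    }
    # open-mate DPQs now (only survivors get a colony)
    if (role == "DPQ") {
      open_mate_batch(st, ids[st$mate[ids] == 0L])
    }
    # worker groups in one batch
    nd <- cfg$params$n_drones
    mates <- st$mate[ids]
    open_m <- ped$kind[mates] == KIND_PSEUDO_SIRE
    c2 <- ifelse(open_m, 1, 0.5)
    dd <- ifelse(open_m,
                 open_mating_mean_var(nd, ped$n_dummy_dpq) -
                   pseudo_sire_var(ped$n_dummy_dpq),
                 0.25 * (1 - ped$F[mates]) / nd)
    wg <- ped_add_batch(ped, rep(KIND_WORKER_GROUP, length(ids)),
                        ids, mates, rep(as.integer(birth_year), length(ids)),
                        rep(NA_real_, length(ids)),
                        rep(0.5, length(ids)), c2, dd)
    all_rows <- rep((ids - 1L) * nd, each = nd) + seq_len(nd)
    drone_means <- rowsum(st$drone_mat[all_rows, , drop = FALSE],
                          rep(seq_along(ids), each = nd)) / nd
    wbv <- 0.5 * st$bv[ids, , drop = FALSE] + drone_means
    bv_grow(st, ped$n); meta_grow(st, ped$n)
    st$bv[wg, ] <- wbv
    st$phenotyped[ids] <- TRUE
    st$wg_lookup[ids] <- wg
    y <- colony_phenotype(st$bv[ids, , drop = FALSE], wbv,
                          E[st$apiary[ids], , drop = FALSE],
                          cfg$params, traits_to_record = traits)
    av1 <- if (1L %in% traits) avail[match(1L, traits)] else NA_integer_
    av2 <- if (2L %in% traits) avail[match(2L, traits)] else NA_integer_
    st$perf[[length(st$perf) + 1L]] <- data.frame(
      queen = ids, worker_group = wg, apiary = st$apiary[ids],
      year = test_year, y_T1 = y[, 1L], y_T2 = y[, 2L],
      avail_T1 = av1, avail_T2 = av2,
      role = role, birth_year = birth_year)
    ap_counts <- ap_counts + tabulate(st$apiary[ids], cfg$n_apiaries)
  }
  st$ledger$apiary[[length(st$ledger$apiary) + 1L]] <-
    data.frame(year = test_year, apiary = seq_len(cfg$n_apiaries),
               colonies = ap_counts)
  invisible(st)
}

# --- evaluation --------------------------------------------------------

perf_table <- function(st) {
  do.call(rbind, st$perf)
}

# performance file as of an evaluation year (availability filter)
perf_available <- function(st, year) {
  pf <- perf_table(st)
  if (is.null(pf)) return(NULL)
  pf$y_T1[is.na(pf$avail_T1) | pf$avail_T1 > year] <- NA
  pf$y_T2[is.na(pf$avail_T2) | pf$avail_T2 > year] <- NA
  pf[!(is.na(pf$y_T1) & is.na(pf$y_T2)), , drop = FALSE]
}

# inverse relationship matrix over the ancestrally closed evaluation
# subset (phenotyped queens, their worker groups and pseudo-sires)
eval_ainv <- function(st, perf) {
  ped <- st$ped
  n <- ped$n
  keep <- logical(n)
  keep[perf$queen] <- TRUE
  keep[perf$worker_group] <- TRUE
  # ancestors: walk backwards (parents precede children)
  for (i in n:1) {
    if (keep[i]) {
      if (ped$dam[i] > 0L) keep[ped$dam[i]] <- TRUE
      if (ped$sire[i] > 0L) keep[ped$sire[i]] <- TRUE
    }
  }
  idx <- which(keep)
  map <- integer(n); map[idx] <- seq_along(idx)
  dam <- ped$dam[idx]; sire <- ped$sire[idx]
  dam2 <- ifelse(dam > 0L, map[pmax(dam, 1L)], 0L)
  sire2 <- ifelse(sire > 0L, map[pmax(sire, 1L)], 0L)
  sub <- list(n = length(idx), dam = dam2, sire = sire2,
              c1 = ped$c1[idx], c2 = ped$c2[idx], d = ped$d[idx])
  class(sub) <- "bee_pedigree_sub"
  Ainv <- ainv_from_arrays(sub$dam, sub$sire, sub$c1, sub$c2, sub$d)
  list(Ainv = Ainv, idx = idx, map = map)
}

# Henderson assembly from raw recursion arrays (shared with
# compute_A_inverse)
ainv_from_arrays <- function(dam, sire, c1, c2, d) {
  n <- length(dam)
  idx <- seq_len(n)
  w <- 1 / d
  has1 <- dam > 0L; has2 <- sire > 0L; has12 <- has1 & has2
  ii <- c(idx, idx[has1], dam[has1], idx[has2], sire[has2],
          dam[has12], sire[has12], dam[has1], sire[has2])
  jj <- c(idx, dam[has1], idx[has1], sire[has2], idx[has2],
          sire[has12], dam[has12], dam[has1], sire[has2])
  xx <- c(w, -c1[has1] * w[has1], -c1[has1] * w[has1],
          -c2[has2] * w[has2], -c2[has2] * w[has2],
          (c1 * c2 * w)[has12], (c1 * c2 * w)[has12],
          (c1^2 * w)[has1], (c2^2 * w)[has2])
  Matrix::forceSymmetric(Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                              dims = c(n, n)))
}

# Run the genetic evaluation as of `year`. In "known" mode the true G and
# R are used; in "reml" mode variances are re-estimated first (start
# values 0.9x genetic / 1.1x residual of the truth) and a convergence
# failure marks the replicate as failed.
evaluate_population <- function(st, year) {
  cfg <- st$cfg
  pf <- perf_available(st, year)
  st$ledger$eval[[length(st$ledger$eval) + 1L]] <-
    data.frame(year = year, n_T1 = sum(!is.na(pf$y_T1)),
               n_T2 = sum(!is.na(pf$y_T2)))
  # bookkeeping-only mode and the random-selection (drift) control skip
  # the genetic evaluation entirely
  if (cfg$evaluation == "dry" || all(cfg$weights == 0)) {
    return(list(fit = NULL, map = NULL))
  }
  ae <- eval_ainv(st, pf)
  pf2 <- pf
  pf2$queen <- ae$map[pf$queen]
  pf2$worker_group <- ae$map[pf$worker_group]
  G <- st$G; R <- st$R
  if (cfg$evaluation == "reml") {
    est <- reml_estimate(pf2, ae$Ainv, 0.9 * st$G, 1.1 * st$R)
    st$reml[[as.character(year)]] <- list(converged = est$converged,
                                          iterations = est$iterations)
    if (!est$converged) {
      st$failed <- TRUE
      return(NULL)
    }
    G <- est$G; R <- est$R
  }
  # exact speed-up: with block-diagonal G and R across traits and a
  # single-trait goal, only the weighted trait's records inform ranking
  traits <- NULL
  Gr <- restrict_G(list(k = 4L, effects = 1:4), G)
  cross0 <- all(Gr[1:2, 3:4] == 0) && (nrow(as.matrix(R)) < 2 ||
                                         as.matrix(R)[1, 2] == 0)
  if (cross0 && any(cfg$weights == 0)) traits <- which(cfg$weights != 0)
  sys <- build_mme(pf2, ae$Ainv, traits = traits)
  fit <- solve_blup(sys, G, R)
  list(fit = fit, map = ae$map, idx = ae$idx, sys = sys)
}

# dam / sire selection from an evaluation
select_parents <- function(st, ev, year, dam_candidates, sire_candidates) {
  cfg <- st$cfg
  ped <- st$ped
  # dam index: worker-group EBVs of the candidate's own colony
  dam_wg <- st$wg_lookup[dam_candidates]
  stopifnot(all(dam_wg > 0L))
  if (is.null(ev$fit)) {            # dry run / drift control
    dam_idx <- stats::runif(length(dam_candidates))
    sire_idx <- stats::runif(length(sire_candidates))
  } else {
    dam_idx <- selection_index(ev$fit$ebv, ev$map[dam_wg], cfg$weights)
    sire_idx <- selection_index(ev$fit$ebv, ev$map[sire_candidates], cfg$weights)
  }
  dams <- dam_candidates[order(-dam_idx, dam_candidates)][seq_len(cfg$n_selected)]
  sires <- sire_candidates[order(-sire_idx, sire_candidates)][seq_len(cfg$n_selected)]
  # accuracies: correlation of true vs estimated index over candidates
  if (!is.null(ev$fit)) {
    true_dam <- selection_index(named_bv(st, dam_wg), seq_along(dam_wg),
                                cfg$weights)
    true_sire <- selection_index(named_bv(st, sire_candidates),
                                 seq_along(sire_candidates), cfg$weights)
    st$accuracy[[as.character(year)]] <- list(
      dam = index_accuracy(true_dam, dam_idx),
      sire = index_accuracy(true_sire, sire_idx))
  }
  st$selected[[as.character(year)]] <- list(dams = dams, sires = sires)
  list(dams = dams, sires = sires)
}

named_bv <- function(st, ids) {
  m <- st$bv[ids, , drop = FALSE]
  colnames(m) <- bv_names()
  m
}

# phenotypic selection index used during Initialization: weighted sum of
# within-cohort standardized phenotypes
phenotypic_index <- function(st, ids, weights) {
  if (all(weights == 0)) return(stats::runif(length(ids)))
  pf <- perf_table(st)
  pf <- pf[match(ids, pf$queen), ]
  z1 <- (pf$y_T1 - mean(pf$y_T1)) / stats::sd(pf$y_T1)
  z2 <- (pf$y_T2 - mean(pf$y_T2)) / stats::sd(pf$y_T2)
  weights[1] * z1 + weights[2] * z2
}
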