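#' Run the Initialization phase
#'
#' Builds the shared starting population: 24 unrelated, non-inbred founder
#' breeding queens in year 1, open-mated to base drones; cohorts of 432
#' candidate BQs and 432 candidate DPQs born every even year from year 2
#' to year 10; 25% random elimination before phenotyping and another 25%
#' after; phenotypic truncation selection of the best 24 per path on the
#' weighted sum of within-cohort standardized phenotypes of both traits.
#' From the year-4 cohort onwards new BQs are inseminated by a single
#' selected DPQ each (closing the population); DPQs are always open-mated.
#'
#' The returned state ends with the year-10 cohort born and reduced by its
#' first mortality, ready for either [run_base()] or [run_alt()] (which
#' perform its phenotyping under their own recording rules).
#'
#' @param cfg a [scheme_config()].
#' @return a `population_state`.
#' @export
run_initialization <- function(cfg) {
  st <- new_population_state(cfg)
  founders <- add_founders(st)
  # founders are phenotyped in year 2 while their first offspring cohort
  # is produced (open matings: no sire pool yet)
  phenotype_cohort(st, 1L, avail_bq = c(2L, 3L))
  produce_cohort(st, founders, 2L, sire_pool = integer(0))
  first_mortality(st, 2L)
  # open-mate the surviving year-2 BQs (no selected DPQs exist yet)
  co2 <- st$cohorts[["2"]]
  open_mate_batch(st, co2$BQ)
  open_mate_batch(st, co2$DPQ)
  last_sel <- NULL
  for (by in seq(2L, cfg$init_end - 2L, by = 2L)) {
    # test year by+1: phenotype both traits, second elimination, select
    phenotype_cohort(st, by)
    co <- second_mortality(st, by)
    idx_bq <- phenotypic_index(st, co$BQ, cfg$weights)
    idx_dpq <- phenotypic_index(st, co$DPQ, cfg$weights)
    dams <- co$BQ[order(-idx_bq, co$BQ)][seq_len(cfg$n_selected)]
    sires <- co$DPQ[order(-idx_dpq, co$DPQ)][seq_len(cfg$n_selected)]
    st$selected[[as.character(by + 2L)]] <- list(dams = dams, sires = sires)
    last_sel <- list(dams = dams, sires = sires)
    # reproduction in year by+2
    produce_cohort(st, dams, by + 2L, sire_pool = sires)
    first_mortality(st, by + 2L)
  }
  st$init_selected <- last_sel
  st
}

#' Run the Base breeding scheme on an initialized population
#'
#' Biennial cycles with a 2-year generation interval on both paths and
#' complete phenotyping: in every odd year the newest cohort is phenotyped
#' on both traits and suffers its second mortality; in every even year
#' from 12 to 30 a genetic evaluation is run (REML + BLUP, or BLUP at the
#' true parameters), the best 24 dams are chosen on their worker-group
#' EBV index among 243 candidates, the best 24 sires on their own EBV
#' index, and a new cohort is born.
#'
#' @param state a `population_state` from [run_initialization()]. The
#'   state is advanced in place and returned.
#' @return the completed state (check `$failed` for REML failures).
#' @export
run_base <- function(state) {
  cfg <- state$cfg
  for (y in (cfg$init_end + 1L):cfg$end_year) {
    if (y %% 2L == 1L) {
      phenotype_cohort(state, y - 1L)
      second_mortality(state, y - 1L)
    } else {
      ev <- evaluate_population(state, y)
      if (is.null(ev)) return(state)      # REML failure
      co <- state$cohorts[[as.character(y - 2L)]]
      sel <- select_parents(state, ev, y, co$BQ, co$DPQ)
      produce_cohort(state, sel$dams, y, sire_pool = sel$sires)
      first_mortality(state, y)
    }
  }
  state
}

#' Run the Alternative breeding scheme on an initialized population
#'
#' Annual dam cycles with a 1-year dam generation interval and partial
#' phenotyping: candidate dams are phenotyped on the early trait only and
#' selected at 1 year old among 324 (one mortality event), while
#' candidate sires keep the 2-year interval with complete phenotyping and
#' selection among 243. Records of 1-year-old DPQs enter the performance
#' file only the following year, together with their late trait. In the
#' transition year 11 the new queens are mated by the DPQ pool selected at
#' the end of Initialization (born in year 8); afterwards queens are
#' always mated by 2-year-old DPQs.
#'
#' @inheritParams run_base
#' @return the completed state (check `$failed` for REML failures).
#' @export
run_alt <- function(state) {
  cfg <- state$cfg
  for (y in (cfg$init_end + 1L):cfg$end_year) {
    by <- y - 1L   # cohort under test this year
    # partial phenotyping on the dam path; DPQ records delayed one year
    phenotype_cohort(state, by,
                     traits_bq = 1L, traits_dpq = c(1L, 2L),
                     avail_bq = y, avail_dpq = c(y + 1L, y + 1L))
    ev <- evaluate_population(state, y)
    if (is.null(ev)) return(state)
    dam_cand <- state$cohorts[[as.character(by)]]$BQ    # 324 one-year-olds
    if (y == cfg$init_end + 1L) {
      sires <- state$init_selected$sires                # born init_end - 2
      sire_cand <- NULL
    } else {
      sire_cand <- state$cohorts[[as.character(y - 2L)]]$DPQ  # 243 two-year-olds
    }
    if (is.null(sire_cand)) {
      # transition year: only dams are selected
      dam_wg <- state$wg_lookup[dam_cand]
      if (is.null(ev$fit)) {
        dam_idx <- stats::runif(length(dam_cand))
      } else {
        dam_idx <- selection_index(ev$fit$ebv, ev$map[dam_wg], cfg$weights)
        true_dam <- selection_index(named_bv(state, dam_wg),
                                    seq_along(dam_wg), cfg$weights)
        state$accuracy[[as.character(y)]] <- list(
          dam = index_accuracy(true_dam, dam_idx), sire = NA_real_)
      }
      dams <- dam_cand[order(-dam_idx, dam_cand)][seq_len(cfg$n_selected)]
      state$selected[[as.character(y)]] <- list(dams = dams, sires = sires)
      sel <- list(dams = dams, sires = sires)
    } else {
      sel <- select_parents(state, ev, y, dam_cand, sire_cand)
    }
    produce_cohort(state, sel$dams, y, sire_pool = sel$sires)
    first_mortality(state, y)
    # second mortality ends the candidacy of this year's tested DPQs
    second_mortality(state, by, roles = "DPQ")
  }
  state
}

#' Run one paired Base/Alt replicate
#'
#' Runs a single Initialization and advances two deep copies of its state
#' through the Base and the Alternative scheme, using named random
#' sub-streams derived from the replicate seed so the shared phase is
#' bit-identical across the pair.
#'
#' @param cfg a [scheme_config()]; its `scheme` field is ignored (both are
#'   run).
#' @param seed integer replicate seed.
#' @return list with `base` and `alt` completed states and the shared
#'   `init` state, plus per-scheme [replicate_summary()] tables.
#' @export
run_replicate <- function(cfg, seed) {
  set.seed(derive_seed(seed, "init"))
  init <- run_initialization(cfg)
  base_st <- clone_population(init)
  set.seed(derive_seed(seed, "base"))
  base_st <- run_base(base_st)
  alt_st <- clone_population(init)
  set.seed(derive_seed(seed, "alt"))
  alt_st <- run_alt(alt_st)
  out <- list(init = init, base = base_st, alt = alt_st, seed = seed,
              failed = base_st$failed || alt_st$failed)
  out$summary_base <- if (!base_st$failed) replicate_summary(base_st) else NULL
  out$summary_alt <- if (!alt_st$failed) replicate_summary(alt_st) else NULL
  class(out) <- "scheme_replicate"
  out
}

#' @export
print.scheme_replicate <- function(x, ...) {
  cat(sprintf("scheme_replicate (seed %d): %s\n", x$seed,
              if (x$failed) "FAILED (REML non-convergence)" else "complete"))
  invisible(x)
}

#' Deterministic sub-stream seeds
#'
#' Derives reproducible integer seeds below 2^31 from a master seed and a
#' set of string labels, so that independent parts of a simulation draw
#' from decoupled streams.
#'
#' @param seed master integer seed.
#' @param ... character labels.
#' @return integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(as.character(seed), ...), collapse = "/")
  h <- 5381
  for (b in utf8ToInt(lab)) h <- (h * 33 + b) %% 2147483629
  as.integer(h)
}

#' Per-replicate trajectory summary
#'
#' Extracts, per birth year of the candidate-dam cohorts, the mean true
#' breeding values (per trait, per effect, and for the breeding goal) and
#' the mean inbreeding coefficient, expressed both raw and as change
#' against the year-10 cohort; plus the final-year index accuracies and
#' the REML convergence record.
#'
#' @param state a completed `population_state`.
#' @param reference_year cohort used as the zero point (default: the
#'   configuration's `init_end`).
#' @return list with a `trajectory` data.frame and scalars.
#' @export
replicate_summary <- function(state, reference_year = NULL) {
  cfg <- state$cfg
  if (is.null(reference_year)) reference_year <- cfg$init_end
  years <- sort(as.integer(names(state$born)))
  rows <- lapply(years, function(y) {
    ids <- state$born[[as.character(y)]]$BQ
    if (!length(ids)) return(NULL)
    bvm <- state$bv[ids, , drop = FALSE]
    H <- cfg$weights[1] * (bvm[, 1] + bvm[, 2]) +
         cfg$weights[2] * (bvm[, 3] + bvm[, 4])
    data.frame(year = y, n = length(ids),
               mean_H = mean(H),
               mean_T1 = mean(bvm[, 1] + bvm[, 2]),
               mean_T2 = mean(bvm[, 3] + bvm[, 4]),
               mean_W1 = mean(bvm[, 1]), mean_Q1 = mean(bvm[, 2]),
               mean_W2 = mean(bvm[, 3]), mean_Q2 = mean(bvm[, 4]),
               mean_F = mean(state$ped$F[ids]))
  })
  tr <- do.call(rbind, rows)
  ref <- tr[tr$year == reference_year, ]
  if (nrow(ref) == 1L) {
    for (cl in c("mean_H", "mean_T1", "mean_T2", "mean_F")) {
      tr[[paste0("gain_", sub("mean_", "", cl))]] <- tr[[cl]] - ref[[cl]]
    }
  }
  acc_years <- as.integer(names(state$accuracy))
  last_acc <- if (length(acc_years)) state$accuracy[[as.character(max(acc_years))]]
              else list(dam = NA_real_, sire = NA_real_)
  reml_tab <- NULL
  if (length(state$reml)) {
    reml_tab <- data.frame(
      year = as.integer(names(state$reml)),
      converged = vapply(state$reml, function(z) z$converged, TRUE),
      iterations = vapply(state$reml, function(z) z$iterations, 1L))
  }
  list(trajectory = tr, reference_year = reference_year,
       final_dam_accuracy = last_acc$dam,
       final_sire_accuracy = last_acc$sire,
       reml = reml_tab, scheme = cfg$scheme)
}

#' Design-arithmetic dry run
#'
#' Runs a full replicate with random selection (weights ignored, EBV step
#' skipped) purely to exercise the cohort, mortality, allocation and
#' record bookkeeping, and returns the ledger: candidate counts, records
#' per trait at each evaluation year, per-apiary colony counts, and
#' selection rates. Deterministic design arithmetic only - no genetics is
#' evaluated.
#'
#' @param cfg a [scheme_config()] (evaluation mode is ignored).
#' @param scheme `"BASE"` or `"ALT"`.
#' @param seed integer seed.
#' @return list of ledger tables.
#' @export
scheme_dry_run <- function(cfg, scheme = c("BASE", "ALT"), seed = 1L) {
  scheme <- match.arg(scheme)
  cfg$evaluation <- "dry"
  set.seed(derive_seed(seed, "init"))
  st <- run_initialization(cfg)
  set.seed(derive_seed(seed, tolower(scheme)))
  st <- if (scheme == "BASE") run_base(st) else run_alt(st)
  ledger_tables(st)
}

# assembled ledger of a state
ledger_tables <- function(st) {
  cand <- lapply(names(st$selected), function(y) {
    s <- st$selected[[y]]
    data.frame(year = as.integer(y), n_dams = length(s$dams),
               n_sires = length(s$sires))
  })
  list(
    cohort = do.call(rbind, st$ledger$cohort),
    eval = do.call(rbind, st$ledger$eval),
    apiary = do.call(rbind, st$ledger$apiary),
    selected = do.call(rbind, cand),
    candidates = data.frame(
      year = as.integer(names(st$cohorts)),
      BQ = vapply(st$cohorts, function(co) length(co$BQ), 1L),
      DPQ = vapply(st$cohorts, function(co) length(co$DPQ), 1L))
  )
}
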