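#' Build a run manifest for a scenario grid
#'
#' Expands the scenario grid (breeding-goal weights x between-trait
#' correlation x worker-queen correlation x parent-number variant) and
#' fixes the replicate count, master seed, evaluation mode and output
#' directory. Every scenario x replicate receives a derived, reproducible
#' seed.
#'
#' @param weights list of length-2 weight vectors.
#' @param r_T1T2 vector of between-trait genetic correlations.
#' @param r_WQ vector of worker-queen genetic correlations.
#' @param variant `24` (18 offspring per dam) and/or `36` (12 per dam).
#' @param n_replicates paired replicates per scenario (default 50).
#' @param seed master seed.
#' @param evaluation `"reml"` or `"known"`.
#' @param out_dir output directory (created on run).
#' @param end_year last birth year (default 30).
#' @return object of class `run_manifest`.
#' @export
run_manifest <- function(weights = list(c(1, 0), c(0.75, 0.25), c(0.5, 0.5),
                                        c(0.25, 0.75), c(0, 1)),
                         r_T1T2 = c(-0.6, -0.3, 0, 0.3, 0.6),
                         r_WQ = 0, variant = 24L,
                         n_replicates = 50L, seed = 1L,
                         evaluation = c("reml", "known"),
                         out_dir = "apisim-results", end_year = 30L) {
  evaluation <- match.arg(evaluation)
  grid <- expand.grid(w = seq_along(weights), r12 = r_T1T2, rwq = r_WQ,
                      variant = variant, stringsAsFactors = FALSE)
  scenarios <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$variant[i]
    list(weights = weights[[grid$w[i]]], r_T1T2 = grid$r12[i],
         r_WQ = grid$rwq[i], variant = v,
         n_selected = if (v == 36L) 36L else 24L,
         offspring_per_dam = if (v == 36L) 12L else 18L,
         label = sprintf("H%g-%g_r%+.1f_rwq%+.1f_v%d",
                         weights[[grid$w[i]]][1], weights[[grid$w[i]]][2],
                         grid$r12[i], grid$rwq[i], v))
  })
  structure(list(scenarios = scenarios, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), evaluation = evaluation,
                 out_dir = out_dir, end_year = as.integer(end_year)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d scenarios x %d replicates (%s evaluation), seed %d\n",
              length(x$scenarios), x$n_replicates, x$evaluation, x$seed))
  invisible(x)
}

#' Execute a manifest of paired Base/Alt scenarios
#'
#' Runs every scenario of the manifest: paired replicates share their
#' Initialization; a replicate whose REML fails to converge in either
#' scheme is recorded as failed and a fresh replicate (next derived seed)
#' is drawn in its place. Per-replicate trajectories, the scenario
#' comparison table and the manifest itself are written as CSV/JSON under
#' the output directory.
#'
#' @param manifest a [run_manifest()].
#' @param quiet suppress progress messages.
#' @return named list of [scenario_comparison()] objects, invisibly.
#' @export
run_grid <- function(manifest, quiet = FALSE) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_json <- file.path(manifest$out_dir, "manifest.json")
  jsonlite::write_json(
    list(n_replicates = manifest$n_replicates, seed = manifest$seed,
         evaluation = manifest$evaluation, end_year = manifest$end_year,
         scenarios = lapply(manifest$scenarios, function(s)
           s[c("weights", "r_T1T2", "r_WQ", "variant", "label")])),
    manifest_json, auto_unbox = TRUE, digits = NA)
  results <- list()
  log_lines <- character(0)
  for (sc in manifest$scenarios) {
    gp <- genetic_params(r_WQ = sc$r_WQ, r_T1T2 = sc$r_T1T2)
    cfg <- scheme_config(weights = sc$weights, params = gp,
                         n_selected = sc$n_selected,
                         offspring_per_dam = sc$offspring_per_dam,
                         end_year = manifest$end_year,
                         evaluation = manifest$evaluation)
    reps <- list()
    attempt <- 0L
    n_failed <- 0L
    while (length(reps) < manifest$n_replicates && attempt < 4L * manifest$n_replicates) {
      attempt <- attempt + 1L
      seed_r <- derive_seed(manifest$seed, sc$label, attempt)
      t0 <- proc.time()[3]
      r <- run_replicate(cfg, seed_r)
      dt <- proc.time()[3] - t0
      if (r$failed) {
        n_failed <- n_failed + 1L
        log_lines <- c(log_lines, sprintf(
          "%s attempt %d seed %d FAILED (REML) after %.1fs", sc$label,
          attempt, seed_r, dt))
        next
      }
      reps[[length(reps) + 1L]] <- r
      log_lines <- c(log_lines, sprintf(
        "%s attempt %d seed %d ok (%.1fs)", sc$label, attempt, seed_r, dt))
      if (!quiet) message(sprintf("[%s] replicate %d/%d done (%.1fs)",
                                  sc$label, length(reps),
                                  manifest$n_replicates, dt))
    }
    cmp <- scenario_comparison(reps)
    cmp$n_failed <- n_failed
    results[[sc$label]] <- cmp
    # tidy per-replicate trajectories
    tidy <- do.call(rbind, lapply(reps, function(r) {
      rbind(
        cbind(scenario = sc$label, replicate = r$seed, scheme = "BASE",
              r$summary_base$trajectory),
        cbind(scenario = sc$label, replicate = r$seed, scheme = "ALT",
              r$summary_alt$trajectory))
    }))
    data.table::fwrite(tidy, file.path(manifest$out_dir,
                                       paste0(sc$label, "_trajectories.csv")))
    data.table::fwrite(cmp$table, file.path(manifest$out_dir,
                                            paste0(sc$label, "_comparison.csv")))
  }
  writeLines(log_lines, file.path(manifest$out_dir, "run.log"))
  if (!length(results)) return(invisible(results))
  # aggregate comparison table across scenarios
  agg <- do.call(rbind, lapply(names(results), function(lb) {
    x <- results[[lb]]
    data.frame(scenario = lb, n = x$n, n_failed = x$n_failed,
               base_gain_H = x$H$mean_base, alt_gain_H = x$H$mean_alt,
               rel_diff_H = x$H$mean_rel_diff, se_rel_diff_H = x$H$se_rel_diff,
               p_hat_H = x$H$p$p_hat, p_se_H = x$H$p$se_label,
               base_added_F = x$added_F$mean_base,
               alt_added_F = x$added_F$mean_alt,
               rel_diff_F = x$added_F$mean_rel_diff)
  }))
  data.table::fwrite(agg, file.path(manifest$out_dir, "scenario_summary.csv"))
  invisible(results)
}

#' Write a performance file as CSV
#'
#' Columns `colony_id`, `queen_id`, `worker_group_id`, `apiary`, `year`,
#' `y_T1`, `y_T2` (empty = missing), the standing interchange format of
#' the evaluation module.
#'
#' @param perf performance data.frame (as held in a population state).
#' @param file path.
#' @export
write_performance_csv <- function(perf, file) {
  df <- data.frame(colony_id = seq_len(nrow(perf)),
                   queen_id = perf$queen, worker_group_id = perf$worker_group,
                   apiary = perf$apiary, year = perf$year,
                   y_T1 = perf$y_T1, y_T2 = perf$y_T2)
  data.table::fwrite(df, file)
  invisible(file)
}

#' @rdname write_performance_csv
#' @export
read_performance_csv <- function(file) {
  df <- data.table::fread(file)
  data.frame(queen = df$queen_id, worker_group = df$worker_group_id,
             apiary = df$apiary, year = df$year,
             y_T1 = df$y_T1, y_T2 = df$y_T2)
}
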