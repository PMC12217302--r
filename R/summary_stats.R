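#' Relative difference between the accelerated and reference scheme
#'
#' `(value in Alt - value in Base) / |value in Base|`, computed within a
#' replicate; replicate values are then averaged across replicates (the
#' mean of per-replicate ratios, not the ratio of means).
#'
#' @param alt_value,base_value numeric vectors (paired by replicate).
#' @return signed ratio(s); `NA` with a warning where the base value is 0.
#' @export
relative_difference <- function(alt_value, base_value) {
  out <- (alt_value - base_value) / abs(base_value)
  if (any(base_value == 0, na.rm = TRUE)) {
    warning("relative difference undefined where the base value is 0")
    out[base_value == 0] <- NA_real_
  }
  out
}

#' Empirical superiority probability with binomial standard error
#'
#' Share of paired replicates in which the accelerated scheme achieved a
#' strictly higher outcome than the reference scheme, with
#' `SE = sqrt(p(1-p)/n)`. The SE is not estimable when the estimate is 0
#' or 1 (reported as `NA` with flag `"NE"`).
#'
#' @param alt_values,base_values paired replicate outcomes.
#' @return list with `p_hat`, `se` (NA when non-estimable), `se_label`
#'   (formatted, `"NE"` when non-estimable), and `n`.
#' @export
empirical_probability <- function(alt_values, base_values) {
  stopifnot(length(alt_values) == length(base_values), length(alt_values) >= 1)
  n <- length(alt_values)
  p <- mean(alt_values > base_values)
  se <- sqrt(p * (1 - p) / n)
  ne <- p %in% c(0, 1)
  if (n == 1L) ne <- TRUE    # degenerate: single replicate
  list(p_hat = p, se = if (ne) NA_real_ else se,
       se_label = if (ne) "NE" else formatC(se, digits = 2, format = "f"),
       n = n)
}

#' Expected selection intensity of truncation selection
#'
#' Expected mean, in standard-deviation units, of the top `k` order
#' statistics of `n` i.i.d. standard normal candidates, by numerical
#' integration of the order-statistic densities (exact finite-sample
#' value, not the infinite-population approximation).
#'
#' @param k number selected.
#' @param n number of candidates.
#' @return expected selection intensity (SD units).
#' @examples
#' expected_selection_intensity(24, 243)   # about 1.76
#' expected_selection_intensity(24, 324)   # about 1.89
#' @export
expected_selection_intensity <- function(k, n) {
  stopifnot(k >= 1, n >= 1, k <= n)
  if (k == n) return(0)
  # E[X_(i)] for the i-th of n standard normal order statistics
  e_order <- function(i) {
    stats::integrate(function(x) {
      lw <- lchoose(n, i) + log(i) + (i - 1) * stats::pnorm(x, log.p = TRUE) +
        (n - i) * stats::pnorm(x, lower.tail = FALSE, log.p = TRUE)
      x * exp(lw + stats::dnorm(x, log = TRUE))
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  mean(vapply((n - k + 1L):n, e_order, 1))
}

#' Inbreeding rates per year and per generation
#'
#' Turns an inbreeding trajectory into average rates over the selection
#' period: change in mean F per year, and per generation using the
#' scheme's realized generation count over the same period.
#'
#' @param trajectory data.frame with columns `year` and `mean_F` (as from
#'   [replicate_summary()]).
#' @param from,to bounding birth years (default: first and last).
#' @param generations number of generations realized between `from` and
#'   `to` (10 for the reference scheme's 20 years, 20 dam generations for
#'   the accelerated scheme; an averaged dam/sire count may be supplied).
#' @return list with `per_year` and `per_generation` rates (on the F
#'   scale).
#' @export
inbreeding_rates <- function(trajectory, from = NULL, to = NULL, generations) {
  stopifnot(nrow(trajectory) >= 2)
  if (is.null(from)) from <- min(trajectory$year)
  if (is.null(to)) to <- max(trajectory$year)
  F0 <- trajectory$mean_F[trajectory$year == from]
  F1 <- trajectory$mean_F[trajectory$year == to]
  if (!length(F0) || !length(F1)) stop("bounding years missing from trajectory")
  dF <- F1 - F0
  list(per_year = dF / (to - from), per_generation = dF / generations)
}

#' Aggregate paired replicates into a scenario comparison
#'
#' Collects per-replicate long-term outcomes of paired Base/Alt runs and
#' computes the comparison statistics: mean gains, added inbreeding, mean
#' within-replicate relative differences with standard errors, and the
#' empirical probability of the accelerated scheme outperforming the
#' reference for the breeding goal and per trait.
#'
#' @param replicates list of [run_replicate()] results (failed ones are
#'   dropped).
#' @param final_year evaluation horizon (default: the configured end
#'   year).
#' @return object of class `scenario_comparison`: a per-replicate table
#'   and aggregated statistics.
#' @export
scenario_comparison <- function(replicates, final_year = NULL) {
  ok <- Filter(function(r) !r$failed, replicates)
  if (!length(ok)) stop("no successful replicates")
  rows <- lapply(ok, function(r) {
    fy <- if (is.null(final_year)) max(r$summary_base$trajectory$year) else final_year
    tb <- r$summary_base$trajectory; ta <- r$summary_alt$trajectory
    pick <- function(tr, col) tr[[col]][tr$year == fy]
    data.frame(seed = r$seed,
               base_gain_H = pick(tb, "gain_H"), alt_gain_H = pick(ta, "gain_H"),
               base_gain_T1 = pick(tb, "gain_T1"), alt_gain_T1 = pick(ta, "gain_T1"),
               base_gain_T2 = pick(tb, "gain_T2"), alt_gain_T2 = pick(ta, "gain_T2"),
               base_added_F = pick(tb, "gain_F"), alt_added_F = pick(ta, "gain_F"))
  })
  tab <- do.call(rbind, rows)
  agg <- function(a, b) {
    rd <- relative_difference(a, b)
    list(mean_base = mean(b), se_base = stats::sd(b) / sqrt(length(b)),
         mean_alt = mean(a), se_alt = stats::sd(a) / sqrt(length(a)),
         mean_rel_diff = mean(rd), se_rel_diff = stats::sd(rd) / sqrt(length(rd)),
         p = empirical_probability(a, b))
  }
  out <- list(
    n = nrow(tab), table = tab,
    H = agg(tab$alt_gain_H, tab$base_gain_H),
    T1 = agg(tab$alt_gain_T1, tab$base_gain_T1),
    T2 = agg(tab$alt_gain_T2, tab$base_gain_T2),
    added_F = agg(tab$alt_added_F, tab$base_added_F)
  )
  class(out) <- "scenario_comparison"
  out
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("scenario_comparison over %d paired replicates\n", x$n))
  f <- function(nm, a) {
    cat(sprintf(
      "  %-8s base %6.2f +/- %.2f | alt %6.2f +/- %.2f | rel diff %+.1f%% +/- %.1f%% | p^ %.2f (%s)\n",
      nm, a$mean_base, a$se_base, a$mean_alt, a$se_alt,
      100 * a$mean_rel_diff, 100 * a$se_rel_diff, a$p$p_hat, a$p$se_label))
  }
  f("gain H", x$H); f("gain T1", x$T1); f("gain T2", x$T2)
  cat(sprintf(
    "  added F  base %5.2f%% +/- %.2f | alt %5.2f%% +/- %.2f | rel diff %+.1f%% +/- %.1f%%\n",
    100 * x$added_F$mean_base, 100 * x$added_F$se_base,
    100 * x$added_F$mean_alt, 100 * x$added_F$se_alt,
    100 * x$added_F$mean_rel_diff, 100 * x$added_F$se_rel_diff))
  invisible(x)
}
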