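#' Configuration of a breeding-scheme scenario
#'
#' Collects all design constants of one simulated scenario. The defaults
#' reproduce the focal design: 24 selected breeding queens (BQs) and 24
#' selected drone-producing queens (DPQs) per cycle, 18 surviving
#' offspring of each type per selected dam (so 432 candidates born per
#' path and cycle), 25% random mortality applied twice before selection
#' at 2 years (once before selection at 1 year), 18 test apiaries with
#' each sister group split over 3 of them, selection from year 10 to year
#' 30. The 36-parent variant uses 36 selected queens per path and sister
#' groups of 12.
#'
#' @param scheme `"BASE"` or `"ALT"`.
#' @param weights length-2 breeding-goal weights on the early and late
#'   trait, from the grid (1:0), (0.75:0.25), (0.5:0.5), (0.25:0.75),
#'   (0:1).
#' @param params a [genetic_params()] object.
#' @param n_selected number of selected BQs (= selected DPQs) per cycle.
#' @param offspring_per_dam offspring BQs (= offspring DPQs) per selected
#'   dam.
#' @param mortality_rate yearly random colony loss, applied as an exact
#'   fraction of each cohort.
#' @param n_apiaries number of test apiaries.
#' @param apiaries_per_group apiaries over which one sister group is
#'   split.
#' @param init_end last year of the Initialization phase.
#' @param end_year last birth year simulated.
#' @param evaluation `"reml"` for in-loop variance re-estimation before
#'   every selection, `"known"` to evaluate at the true parameters
#'   (faster; used for scaled-down runs and tests).
#' @param n_founders founder breeding queens in year 1.
#' @return object of class `scheme_config`.
#' @export
scheme_config <- function(scheme = c("BASE", "ALT"), weights = c(0.5, 0.5),
                          params = genetic_params(),
                          n_selected = 24L, offspring_per_dam = 18L,
                          mortality_rate = 0.25, n_apiaries = 18L,
                          apiaries_per_group = 3L,
                          init_end = 10L, end_year = 30L,
                          evaluation = c("reml", "known"),
                          n_founders = 24L) {
  scheme <- match.arg(scheme)
  evaluation <- match.arg(evaluation)
  cfg <- structure(list(
    scheme = scheme, weights = as.numeric(weights), params = params,
    n_selected = as.integer(n_selected),
    offspring_per_dam = as.integer(offspring_per_dam),
    mortality_rate = mortality_rate, n_apiaries = as.integer(n_apiaries),
    apiaries_per_group = as.integer(apiaries_per_group),
    init_end = as.integer(init_end), end_year = as.integer(end_year),
    evaluation = evaluation, n_founders = as.integer(n_founders)
  ), class = "scheme_config")
  validate_config(cfg)
  cfg
}

#' Validate a scheme configuration
#'
#' Checks the design invariants: feasible apiary allocation (sister groups
#' divisible over their apiaries, apiaries receiving whole groups),
#' integer mortality counts, weights on the 5-point grid (off-grid values
#' warn), and positive-definite genetic parameters.
#'
#' @param cfg a [scheme_config()] (or a bare list with the same fields).
#' @return the validated config, invisibly; errors aggregate all problems.
#' @export
validate_config <- function(cfg) {
  probs <- character(0)
  n_cand <- cfg$n_selected * cfg$offspring_per_dam
  gsize <- cfg$offspring_per_dam
  if (gsize %% cfg$apiaries_per_group != 0L) {
    probs <- c(probs, sprintf(
      "sister group size %d not divisible over %d apiaries",
      gsize, cfg$apiaries_per_group))
  }
  slots <- cfg$n_selected * cfg$apiaries_per_group
  if (slots %% cfg$n_apiaries != 0L) {
    probs <- c(probs, sprintf(
      "%d group-apiary slots cannot be spread evenly over %d apiaries",
      slots, cfg$n_apiaries))
  }
  if (abs(n_cand * cfg$mortality_rate - round(n_cand * cfg$mortality_rate)) > 1e-9) {
    warning("mortality does not remove an integer count; will round")
  }
  grid <- list(c(1, 0), c(0.75, 0.25), c(0.5, 0.5), c(0.25, 0.75), c(0, 1))
  if (!any(vapply(grid, function(g) isTRUE(all.equal(g, cfg$weights)), TRUE))) {
    warning("breeding-goal weights are off the 5-point grid")
  }
  if (!inherits(cfg$params, "genetic_params")) {
    probs <- c(probs, "params must be a genetic_params object")
  } else {
    tryCatch(build_G(cfg$params), error = function(e) {
      probs <<- c(probs, conditionMessage(e))
    })
  }
  if (cfg$init_end >= cfg$end_year) probs <- c(probs, "init_end must precede end_year")
  if (length(probs)) stop(paste(probs, collapse = "; "))
  invisible(cfg)
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf("scheme_config: %s, weights (%g:%g), %s evaluation\n",
              x$scheme, x$weights[1], x$weights[2], x$evaluation))
  cat(sprintf("  %d selected x %d offspring per path; %d apiaries; years 1-%d (init to %d)\n",
              x$n_selected, x$offspring_per_dam, x$n_apiaries, x$end_year,
              x$init_end))
  invisible(x)
}

#' Random elimination of an exact fraction of a cohort
#'
#' Removes `round(rate * n)` members uniformly at random without
#' replacement, reproducing the design's exact candidate counts.
#'
#' @param cohort vector of ids.
#' @param rate elimination fraction.
#' @return the surviving subset, in original order.
#' @export
apply_mortality <- function(cohort, rate) {
  n <- length(cohort)
  k <- rate * n
  if (abs(k - round(k)) > 1e-9) warning("non-integer removal count; rounding")
  k <- as.integer(round(k))
  if (k == 0L) return(cohort)
  drop_idx <- sample.int(n, k)
  cohort[-drop_idx]
}

#' Allocate sister groups to test apiaries
#'
#' Each sister group of `group_size` queens is split evenly over
#' `apiaries_per_group` distinct apiaries, and every apiary receives the
#' same number of groups. The assignment is randomized by permuting group
#' and apiary labels over a cyclic base design.
#'
#' @param n_groups number of sister groups (one per selected dam).
#' @param group_size queens per sister group.
#' @param n_apiaries number of apiaries.
#' @param apiaries_per_group apiaries per sister group.
#' @return integer vector of apiary ids of length `n_groups * group_size`,
#'   ordered by group then within-group position.
#' @export
allocate_apiaries <- function(n_groups, group_size, n_apiaries = 18L,
                              apiaries_per_group = 3L) {
  if (group_size %% apiaries_per_group != 0L ||
      (n_groups * apiaries_per_group) %% n_apiaries != 0L) {
    stop("infeasible apiary design")
  }
  per_ap <- group_size / apiaries_per_group
  # cyclic base design: group g uses apiaries ((g-1)*k .. g*k-1) mod A
  ap_perm <- sample.int(n_apiaries)
  gr_perm <- sample.int(n_groups)
  out <- integer(n_groups * group_size)
  for (g in seq_len(n_groups)) {
    slots <- ((gr_perm[g] - 1L) * apiaries_per_group +
                seq_len(apiaries_per_group) - 1L) %% n_apiaries + 1L
    out[(g - 1L) * group_size + seq_len(group_size)] <-
      rep(ap_perm[slots], each = per_ap)
  }
  out
}

#' Random balanced mating of new queens to selected drone sources
#'
#' Each selected DPQ contributes drones to an equal number of matings; the
#' assignment of DPQs to new breeding queens is uniformly random.
#'
#' @param n_queens number of new queens to mate.
#' @param dpq_ids ids of the selected DPQs.
#' @return vector of length `n_queens` with the assigned DPQ id per queen.
#' @export
mate_cohort <- function(n_queens, dpq_ids) {
  k <- length(dpq_ids)
  per <- n_queens / k
  if (per != round(per)) {
    warning("unbalanced mating: using nearest-balanced assignment")
  }
  pool <- rep(dpq_ids, length.out = n_queens)
  pool[sample.int(n_queens)]
}
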