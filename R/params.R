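#' Genetic parameter set for the two-trait colony model
#'
#' Bundles the base-population variance components used throughout the
#' simulator. Both traits share the same components: the queen-effect
#' additive variance is half the worker-effect additive variance and one
#' third of the residual variance. Apiary-by-year effect variances default
#' to one third (early trait) and two thirds (late trait) of the phenotypic
#' variance \eqn{\sigma^2_P = \sigma^2_{A_W} + \sigma^2_{A_Q} +
#' \sigma^2_\epsilon}.
#'
#' @param sigma2_AW worker-effect additive variance per trait. All output is
#'   expressed in units of this variance (default 1).
#' @param r_WQ genetic correlation between worker and queen effects within a
#'   trait. Field estimates are typically 0 to -0.5.
#' @param r_T1T2 genetic correlation between the early (T1) and late (T2)
#'   trait, applied to both effects via a Kronecker structure.
#' @param sigma2_AQ queen-effect additive variance; defaults to
#'   `sigma2_AW / 2`.
#' @param sigma2_eps residual variance per trait; defaults to
#'   `3 * sigma2_AQ`.
#' @param sigma2_apiary length-2 vector of apiary-by-year effect variances
#'   for the early and late trait.
#' @param n_drones polyandry level: number of drones mating each queen.
#' @param n_dummy_dpq number of unknown, unrelated dummy drone-producing
#'   queens composing each open-mating pseudo-sire.
#'
#' @return An object of class `genetic_params`.
#' @examples
#' gp <- genetic_params()
#' build_G(gp)
#' @export
genetic_params <- function(sigma2_AW = 1, r_WQ = 0, r_T1T2 = 0,
                           sigma2_AQ = sigma2_AW / 2,
                           sigma2_eps = 3 * sigma2_AQ,
                           sigma2_apiary = NULL,
                           n_drones = 8L, n_dummy_dpq = 100L) {
  stopifnot(sigma2_AW > 0, sigma2_AQ > 0, sigma2_eps > 0,
            is.numeric(r_WQ), length(r_WQ) == 1L, abs(r_WQ) <= 1,
            is.numeric(r_T1T2), length(r_T1T2) == 1L, abs(r_T1T2) <= 1,
            n_drones >= 1L, n_dummy_dpq >= 1L)
  sigma2_P <- sigma2_AW + sigma2_AQ + sigma2_eps
  if (is.null(sigma2_apiary)) {
    sigma2_apiary <- c(T1 = sigma2_P / 3, T2 = 2 * sigma2_P / 3)
  }
  stopifnot(length(sigma2_apiary) == 2L, all(sigma2_apiary >= 0))
  structure(list(
    sigma2_AW = sigma2_AW, sigma2_AQ = sigma2_AQ,
    sigma2_eps = sigma2_eps,
    r_WQ = r_WQ, r_T1T2 = r_T1T2,
    sigma2_apiary = stats::setNames(as.numeric(sigma2_apiary), c("T1", "T2")),
    sigma2_P = sigma2_P,
    n_drones = as.integer(n_drones),
    n_dummy_dpq = as.integer(n_dummy_dpq)
  ), class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, ...) {
  cat("Two-trait colony-model genetic parameters\n")
  cat(sprintf("  sigma2_AW = %.4g, sigma2_AQ = %.4g, sigma2_eps = %.4g\n",
              x$sigma2_AW, x$sigma2_AQ, x$sigma2_eps))
  cat(sprintf("  r_WQ = %.2f, r_T1T2 = %.2f\n", x$r_WQ, x$r_T1T2))
  cat(sprintf("  apiary-by-year variances: T1 = %.4g, T2 = %.4g\n",
              x$sigma2_apiary[1], x$sigma2_apiary[2]))
  cat(sprintf("  polyandry = %d drones; pseudo-sire pool = %d dummy DPQs\n",
              x$n_drones, x$n_dummy_dpq))
  invisible(x)
}

#' Additive-genetic covariance matrix of the four genetic effects
#'
#' Builds the 4x4 covariance matrix of the effects
#' (worker-T1, queen-T1, worker-T2, queen-T2) as the Kronecker product of
#' the 2x2 between-trait correlation matrix and the 2x2 within-trait
#' worker/queen covariance matrix, with
#' \eqn{\sigma_{A_{WQ}} = r_{WQ}\sqrt{\sigma^2_{A_W}\sigma^2_{A_Q}}}.
#'
#' @param params a [genetic_params()] object.
#' @return Symmetric positive semi-definite 4x4 matrix with dimnames
#'   `c("W1","Q1","W2","Q2")`.
#' @export
build_G <- function(params) {
  stopifnot(inherits(params, "genetic_params"))
  s_wq <- params$r_WQ * sqrt(params$sigma2_AW * params$sigma2_AQ)
  trait_cor <- matrix(c(1, params$r_T1T2, params$r_T1T2, 1), 2, 2)
  effect_cov <- matrix(c(params$sigma2_AW, s_wq, s_wq, params$sigma2_AQ), 2, 2)
  G <- kronecker(trait_cor, effect_cov)
  dimnames(G) <- list(bv_names(), bv_names())
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("genetic covariance matrix is not positive semi-definite for this ",
         "combination of correlations")
  }
  G
}

#' Residual covariance matrix of the two traits
#'
#' Residuals of the two traits recorded on the same colony are modelled as
#' uncorrelated; only the early/late residual variances enter.
#'
#' @param params a [genetic_params()] object.
#' @return 2x2 diagonal matrix.
#' @export
build_R <- function(params) {
  stopifnot(inherits(params, "genetic_params"))
  R <- diag(rep(params$sigma2_eps, 2))
  dimnames(R) <- list(c("T1", "T2"), c("T1", "T2"))
  R
}

# canonical ordering of the four genetic effects used everywhere
bv_names <- function() c("W1", "Q1", "W2", "Q2")

# indices of (effect, trait) pairs in the length-4 ordering
bv_index <- function(effect = c("W", "Q"), trait) {
  effect <- match.arg(effect)
  stopifnot(trait %in% c(1L, 2L))
  (trait - 1L) * 2L + if (effect == "W") 1L else 2L
}

# multivariate normal draws for a possibly singular covariance (eigen route)
rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  ei <- eigen(Sigma, symmetric = TRUE)
  val <- pmax(ei$values, 0)
  L <- ei$vectors %*% diag(sqrt(val), p)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% t(L)
  colnames(X) <- colnames(Sigma)
  X
}
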