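# Concentration simulation ----------------------------------------------------
#
# Concentrations are strictly positive: independent metabolites are drawn
# from a zero-truncated normal by inverse-CDF; correlated metabolites from
# a multivariate normal by rejection sampling. The user-specified pairwise
# correlation matrix is repaired to the nearest positive semidefinite
# correlation matrix (alternating projections, Higham 2002) before the
# covariance is built, and the covariance diagonal is inflated if needed.

#' Estimate a standard deviation from a mean or half-range
#'
#' When a concentration database reports only a mean (or a half-range)
#' the SD is estimated as that value divided by 1.95.
#'
#' @param mean_or_half_range Non-negative number(s).
#' @return `mean_or_half_range / 1.95`.
#' @export
estimate_sd_from_mean <- function(mean_or_half_range) {
  if (any(!is.finite(mean_or_half_range)) || any(mean_or_half_range < 0))
    stop_validation("mean/half-range must be finite and non-negative")
  mean_or_half_range / 1.95
}

#' Build a case template from fold changes on a control template
#'
#' Each fold scales both the mean and the SD of its metabolite (keeping
#' the coefficient of variation constant); metabolites without a fold are
#' copied unchanged. Set `scale_sd = FALSE` to scale the mean only.
#'
#' @param control A [concentration_template()].
#' @param folds Named numeric vector, metabolite -> positive fold.
#' @param scale_sd Scale SDs by the fold as well? Default `TRUE`.
#' @param group_label Label for the case template.
#' @return A [concentration_template()] for the case group.
#' @export
apply_fold_changes <- function(control, folds, scale_sd = TRUE,
                               group_label = "case") {
  unknown <- setdiff(names(folds), control$metabolite)
  if (length(unknown))
    stop_validation("fold change for metabolite(s) not in template: ",
                    paste(unknown, collapse = ", "))
  if (any(!is.finite(folds)) || any(folds <= 0))
    stop_validation("fold changes must be positive and finite")
  mean <- control$mean
  sd <- control$sd
  idx <- match(names(folds), control$metabolite)
  mean[idx] <- mean[idx] * folds
  if (scale_sd) sd[idx] <- sd[idx] * folds
  concentration_template(control$metabolite, mean, sd,
                         group_label = group_label,
                         units = attr(control, "units"))
}

#' Sample from a zero-truncated normal distribution
#'
#' Draws from N(mu, sigma^2) conditional on being > 0 via the inverse-CDF
#' method: with `alpha = -mu/sigma`, each draw is
#' `mu + sigma * qnorm(pnorm(alpha) + u * (1 - pnorm(alpha)))` for
#' u ~ Uniform(0,1). `sigma = 0` returns `mu` repeated (requires mu > 0).
#'
#' @param mu Mean of the parent normal.
#' @param sigma SD of the parent normal (>= 0).
#' @param n Number of draws.
#' @return Numeric vector of `n` strictly positive draws.
#' @export
sample_truncated_normal <- function(mu, sigma, n) {
  assert_scalar_number(mu, "mu")
  assert_scalar_number(sigma, "sigma", lower = 0)
  assert_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  if (sigma == 0) {
    if (mu <= 0)
      stop_validation("sigma = 0 with mu <= 0: no positive mass")
    return(rep(mu, n))
  }
  p0 <- stats::pnorm(-mu / sigma)
  u <- stats::runif(n)
  draws <- mu + sigma * stats::qnorm(p0 + u * (1 - p0))
  # guard against u rounding to exactly 0 at extreme truncation
  draws[draws <= 0] <- mu + sigma *
    stats::qnorm((p0 + 1) / 2)[rep(1, sum(draws <= 0))]
  draws
}

#' Nearest positive semidefinite correlation matrix
#'
#' Repairs a user-specified correlation matrix to the nearest (Frobenius
#' norm) correlation matrix with minimum eigenvalue >= -1e-10, using
#' alternating projections between the PSD cone and the unit-diagonal
#' affine set with Dykstra's correction. An input that is already PSD is
#' returned unchanged.
#'
#' @param R Symmetric matrix with unit diagonal and entries in [-1, 1].
#' @param tol Stop when the max-norm change between iterations is below
#'   this (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @return The repaired matrix, with attribute `adjusted` (logical) and
#'   `iterations`.
#' @export
nearest_psd_correlation <- function(R, tol = 1e-8, max_iter = 200L) {
  R <- as.matrix(R)
  if (!isSymmetric(R, tol = 1e-12))
    stop_validation("correlation matrix must be symmetric")
  if (any(abs(R) > 1 + 1e-12))
    stop_validation("correlation entries must lie in [-1, 1]")
  if (any(abs(diag(R) - 1) > 1e-12))
    stop_validation("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10) {
    attr(R, "adjusted") <- FALSE
    attr(R, "iterations") <- 0L
    return(R)
  }
  proj_psd <- function(A) {
    e <- eigen(A, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    A2 <- e$vectors %*% (lam * t(e$vectors))
    (A2 + t(A2)) / 2
  }
  proj_unit_diag <- function(A) { diag(A) <- 1; A }
  Y <- R
  dS <- matrix(0, nrow(R), ncol(R))
  for (it in seq_len(max_iter)) {
    Rk <- Y - dS
    X <- proj_psd(Rk)
    dS <- X - Rk
    Ynew <- proj_unit_diag(X)
    delta <- max(abs(Ynew - Y))
    Y <- Ynew
    if (delta < tol) break
  }
  out <- (Y + t(Y)) / 2
  diag(out) <- 1
  ev_out <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_out) < -1e-10) {
    # final tiny eigenvalue clip preserving the unit diagonal
    e <- eigen(out, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    out <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(out))
    out <- out / outer(d, d)
    out <- (out + t(out)) / 2
    diag(out) <- 1
  }
  dimnames(out) <- dimnames(R)
  attr(out, "adjusted") <- TRUE
  attr(out, "iterations") <- it
  out
}

#' Build a covariance matrix from a correlation matrix and SDs
#'
#' `Sigma = diag(sd) %*% R %*% diag(sd)`. If the result is not positive
#' definite its diagonal is inflated by `|lambda_min| + 1e-8 * trace / K`
#' so that downstream Cholesky factorisation succeeds; the inflation
#' amount is recorded in attribute `inflation` for inspection.
#'
#' @param R_psd PSD correlation matrix (e.g. from
#'   [nearest_psd_correlation()]).
#' @param sds Non-negative SD vector, length = nrow(R_psd).
#' @return Covariance matrix with attributes `inflation` and `inflated`.
#' @export
build_covariance <- function(R_psd, sds) {
  R_psd <- as.matrix(R_psd)
  if (length(sds) != nrow(R_psd))
    stop_validation("length(sds) != dimension of correlation matrix")
  if (any(sds < 0)) stop_validation("sds must be non-negative")
  Sigma <- diag(sds, nrow = length(sds)) %*% R_psd %*%
    diag(sds, nrow = length(sds))
  Sigma <- (Sigma + t(Sigma)) / 2
  lam_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  inflation <- 0
  if (lam_min <= 0) {
    inflation <- abs(lam_min) + 1e-8 * sum(diag(Sigma)) / nrow(Sigma)
    diag(Sigma) <- diag(Sigma) + inflation
  }
  dimnames(Sigma) <- dimnames(R_psd)
  attr(Sigma, "inflation") <- inflation
  attr(Sigma, "inflated") <- inflation > 0
  Sigma
}

#' Sample positive correlated concentrations by rejection
#'
#' Draws replicate concentration vectors from N(mu, Sigma) and rejects any
#' vector with a non-positive component, redrawing until exactly `n`
#' vectors are accepted. Fails with an informative error if the estimated
#' acceptance rate falls below `n / max_attempts`.
#'
#' @param mu Mean vector.
#' @param Sigma Positive definite covariance matrix.
#' @param n Number of accepted vectors required.
#' @param max_attempts Total proposal budget (default `1000 * n`).
#' @return n x K matrix of strictly positive concentrations.
#' @export
sample_correlated_concentrations <- function(mu, Sigma, n,
                                             max_attempts = 1000L * n) {
  K <- length(mu)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != K || ncol(Sigma) != K)
    stop_validation("dimension mismatch between mu and Sigma")
  ch <- tryCatch(chol(Sigma),
                 error = function(e)
                   stop_validation("Sigma is not positive definite"))
  accepted <- matrix(NA_real_, 0L, K)
  attempts <- 0L
  batch <- max(n, 64L)
  while (nrow(accepted) < n) {
    if (attempts >= max_attempts)
      stop_validation(
        "rejection sampling acceptance rate below ", n, "/", max_attempts,
        ": the requested means/SDs place most multivariate normal mass at ",
        "non-positive concentrations; increase means or reduce SDs")
    m <- min(batch, max_attempts - attempts)
    Z <- matrix(stats::rnorm(m * K), m, K)
    X <- sweep(Z %*% ch, 2L, mu, `+`)
    ok <- rowSums(X <= 0) == 0L
    accepted <- rbind(accepted, X[ok, , drop = FALSE])
    attempts <- attempts + m
  }
  out <- accepted[seq_len(n), , drop = FALSE]
  colnames(out) <- names(mu)
  out
}

#' Simulate per-replicate metabolite concentrations for one group
#'
#' Independent metabolites are drawn from zero-truncated normals; when a
#' pairwise correlation specification is given, the requested correlation
#' matrix is repaired to the nearest PSD correlation matrix, the
#' covariance is built (with diagonal inflation if needed) and replicate
#' vectors are drawn by multivariate-normal rejection sampling.
#'
#' @param template A [concentration_template()].
#' @param n_replicates Number of replicates.
#' @param correlations Optional data frame from [read_correlation_spec()]
#'   (columns metabolite_a, metabolite_b, r).
#' @param seed Optional seed applied locally.
#' @param max_attempts_factor Rejection-sampling attempts per draw.
#' @return A `concentration_draws` object: list with `draws`
#'   (n x K matrix), `metabolites`, `group_label`, and (when correlated)
#'   `R_requested`, `R_repaired`, `Sigma` matrices actually used.
#' @export
simulate_concentrations <- function(template, n_replicates,
                                    correlations = NULL, seed = NULL,
                                    max_attempts_factor = 1000L) {
  mets <- template$metabolite
  K <- length(mets)
  with_seed(seed, {
    if (is.null(correlations) || nrow(correlations) == 0L) {
      draws <- matrix(NA_real_, n_replicates, K,
                      dimnames = list(NULL, mets))
      for (k in seq_len(K))
        draws[, k] <- sample_truncated_normal(template$mean[k],
                                              template$sd[k], n_replicates)
      res <- list(draws = draws, metabolites = mets,
                  group_label = attr(template, "group_label"),
                  R_requested = NULL, R_repaired = NULL, Sigma = NULL)
    } else {
      validate_correlation_spec(correlations)
      unknown <- setdiff(c(correlations$metabolite_a,
                           correlations$metabolite_b), mets)
      if (length(unknown))
        stop_validation("correlation references unknown metabolite(s): ",
                        paste(unique(unknown), collapse = ", "))
      R <- diag(K)
      dimnames(R) <- list(mets, mets)
      for (i in seq_len(nrow(correlations))) {
        a <- correlations$metabolite_a[i]
        b <- correlations$metabolite_b[i]
        R[a, b] <- R[b, a] <- correlations$r[i]
      }
      R_rep <- nearest_psd_correlation(R)
      Sigma <- build_covariance(R_rep, template$sd)
      draws <- sample_correlated_concentrations(
        stats::setNames(template$mean, mets), Sigma, n_replicates,
        max_attempts = as.integer(max_attempts_factor) * n_replicates)
      res <- list(draws = draws, metabolites = mets,
                  group_label = attr(template, "group_label"),
                  R_requested = R, R_repaired = R_rep, Sigma = Sigma)
    }
    structure(res, class = "concentration_draws")
  })
}

#' @export
print.concentration_draws <- function(x, ...) {
  cat(sprintf("<concentration_draws> group=%s, %d replicates x %d metabolites%s\n",
              x$group_label, nrow(x$draws), length(x$metabolites),
              if (!is.null(x$Sigma)) ", correlated" else ""))
  invisible(x)
}
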