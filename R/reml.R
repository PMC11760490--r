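#' Fit the polygenic null model y = mu + g + e by REML
#'
#' Variance components of \eqn{y = 1\mu + g + e}, \eqn{g \sim N(0,
#' K\sigma^2_g)}, \eqn{e \sim N(0, I\sigma^2_e)}, estimated by restricted
#' maximum likelihood. A single eigendecomposition of K reduces the model to
#' independent coordinates; the restricted likelihood is then profiled over
#' \eqn{\sigma^2_e} and the intercept and maximised over the variance ratio
#' \eqn{\delta = \sigma^2_g/\sigma^2_e} by one-dimensional optimisation of
#' \eqn{\log\delta} (exact for this model class, one O(n^3) step). The
#' \eqn{\sigma^2_g = 0} boundary is checked explicitly; a boundary solution
#' returns a valid fit with zero breeding values and `boundary = TRUE`.
#'
#' @param y numeric phenotype vector (finite values only).
#' @param K a [compute_grm()] result or plain symmetric matrix.
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)`, reused when
#'   several traits share one kinship matrix.
#' @param tol convergence tolerance on log delta.
#' @return list of class `null_model_fit`: `sigma2_g`, `sigma2_e`, `h2_hat`,
#'   `log_restricted_likelihood`, `mu`, `gbv` (GBLUP breeding values
#'   \eqn{\hat g}), `residuals` (\eqn{y - \hat\mu - \hat g}), `boundary`,
#'   and the eigendecomposition (`eig`) for downstream reuse.
#' @export
fit_null_reml <- function(y, K, eig = NULL, tol = 1e-8) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (any(!is.finite(y))) stop("phenotype contains non-finite values")
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, y))
  xt <- drop(crossprod(eig$vectors, rep(1, n)))

  ll_of <- function(log_delta) reml_profile_loglik(exp(log_delta), d, yt, xt)

  opt <- stats::optimize(function(ld) -ll_of(ld),
                         interval = log(c(1e-6, 1e6)), tol = tol)
  delta <- exp(opt$minimum)
  ll <- -opt$objective
  ll0 <- reml_profile_loglik(0, d, yt, xt)
  boundary <- FALSE
  if (ll0 >= ll) {
    delta <- 0
    ll <- ll0
    boundary <- TRUE
  }

  v <- delta * d + 1
  mu <- sum(xt * yt / v) / sum(xt^2 / v)
  rss <- sum((yt - xt * mu)^2 / v)
  sigma2_e <- rss / (n - 1)
  sigma2_g <- delta * sigma2_e
  if (sigma2_e <= 0) stop("degenerate fit: residual variance is zero")

  fit <- structure(list(
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    h2_hat = delta / (1 + delta),
    log_restricted_likelihood = ll,
    mu = mu, boundary = boundary,
    delta = delta, eig = eig
  ), class = "null_model_fit")
  pg <- predict_gbv(fit, y)
  fit$gbv <- pg$gbv
  fit$residuals <- pg$residuals
  fit
}

# profiled restricted log-likelihood at variance ratio delta, in the rotated
# coordinates (d eigenvalues, yt rotated y, xt rotated intercept column)
reml_profile_loglik <- function(delta, d, yt, xt) {
  n <- length(yt)
  v <- delta * d + 1
  xvx <- sum(xt^2 / v)
  mu <- sum(xt * yt / v) / xvx
  rss <- sum((yt - xt * mu)^2 / v)
  sigma2_e <- rss / (n - 1)
  -0.5 * ((n - 1) * (log(2 * pi * sigma2_e) + 1) + sum(log(v)) + log(xvx))
}

#' GBLUP breeding values and residuals from a fitted null model
#'
#' \deqn{\hat g = \sigma^2_g K V^{-1}(y - 1\hat\mu), \quad V = \sigma^2_g K +
#' \sigma^2_e I} computed through the stored eigendecomposition as
#' \eqn{U\,\mathrm{diag}\{\sigma^2_g d_i/(\sigma^2_g d_i + \sigma^2_e)\}\,
#' U^\top (y - 1\hat\mu)}. Residuals are \eqn{y - \hat\mu - \hat g}; these are
#' the phenotypic residuals the association scan regresses on each SNP.
#'
#' @param fit a [fit_null_reml()] result.
#' @param y the phenotype vector the model was fitted to.
#' @return list with `gbv` and `residuals`.
#' @export
predict_gbv <- function(fit, y) {
  stopifnot(inherits(fit, "null_model_fit"))
  d <- pmax(fit$eig$values, 0)
  denom <- fit$sigma2_g * d + fit$sigma2_e
  if (any(denom <= 0)) stop("singular V: cannot form GBLUP predictor")
  shrink <- fit$sigma2_g * d / denom
  r0 <- y - fit$mu
  gbv <- drop(fit$eig$vectors %*% (shrink * crossprod(fit$eig$vectors, r0)))
  list(gbv = gbv, residuals = r0 - gbv)
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf(
    "null_model_fit: sigma2_g = %.4f, sigma2_e = %.4f, h2 = %.3f%s\n",
    x$sigma2_g, x$sigma2_e, x$h2_hat,
    if (x$boundary) " (boundary: sigma2_g = 0)" else ""))
  invisible(x)
}
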