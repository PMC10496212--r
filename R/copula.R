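#' Calibrate a normal distribution to a symmetric 95% confidence interval
#'
#' Expert assumptions for price and adoption are often stated as a central
#' value plus a symmetric 95% confidence interval. This converts such a
#' triple into normal parameters: the mean equals the center and the
#' standard deviation is `(hi - lo) / (2 * qnorm(0.975))`.
#'
#' @param center central value (the mean).
#' @param lo,hi lower and upper 95% confidence bounds; must bracket
#'   `center` strictly and be symmetric about it (to a relative tolerance
#'   of 1e-6 on the half-widths).
#' @return named numeric vector `c(mean = , sd = )`.
#' @examples
#' normal_from_ci(40000, 30000, 50000)  # sd ~ 5102
#' @export
normal_from_ci <- function(center, lo, hi) {
  if (!(lo < center && center < hi))
    stop("confidence bounds must satisfy lo < center < hi", call. = FALSE)
  half_lo <- center - lo
  half_hi <- hi - center
  if (abs(half_lo - half_hi) > 1e-6 * max(half_lo, half_hi))
    stop("confidence interval is not symmetric about the center; ",
         "re-center it before calibrating", call. = FALSE)
  c(mean = center, sd = (hi - lo) / (2 * qnorm(0.975)))
}

#' Gaussian copula specification and sampling
#'
#' `copula_spec()` bundles a correlation matrix with a list of marginal
#' distribution descriptors; `copula_sample()` draws joint samples:
#' latent multivariate normals with the given correlation are mapped to
#' uniforms through the standard normal CDF and then through each
#' marginal's inverse CDF. Bernoulli margins realize success (1) exactly
#' when the uniform falls below the success probability, so correlating
#' the latent normals correlates the binary outcomes.
#'
#' Supported marginal descriptors (lists with a `type` field):
#' * `list(type = "pert", min =, mode =, max =)`
#' * `list(type = "normal", mean =, sd =)` (optional `lower`, `upper`
#'   truncation bounds, applied by inverse-CDF restriction)
#' * `list(type = "lognormal", meanlog =, sdlog =)`
#' * `list(type = "bernoulli", pos =)`
#'
#' @param corr square correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite).
#' @param marginals list of marginal descriptors, one per matrix column.
#' @param spec a `copula_spec`.
#' @param n number of joint draws.
#' @param seed optional integer seed (set before drawing when given).
#' @return `copula_sample()` returns an `n x d` numeric matrix.
#' @examples
#' sp <- copula_spec(matrix(c(1, .5, .5, 1), 2),
#'                   list(list(type = "pert", min = 1, mode = 2, max = 3),
#'                        list(type = "normal", mean = 0, sd = 1)))
#' x <- copula_sample(sp, 1000, seed = 1)
#' @export
copula_spec <- function(corr, marginals) {
  corr <- as.matrix(corr)
  d <- nrow(corr)
  if (ncol(corr) != d) stop("correlation matrix must be square", call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-12)
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-12)
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10)
    stop(sprintf("correlation matrix is not positive semi-definite (smallest eigenvalue %.3g)", ev),
         call. = FALSE)
  if (length(marginals) != d)
    stop("need one marginal descriptor per correlation-matrix column", call. = FALSE)
  structure(list(corr = corr, marginals = marginals), class = "copula_spec")
}

#' @rdname copula_spec
#' @export
copula_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "copula_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- pnorm(latent_normals(n, spec$corr))
  d <- ncol(u)
  out <- matrix(NA_real_, n, d)
  for (j in seq_len(d)) out[, j] <- marginal_quantile(u[, j], spec$marginals[[j]])
  colnames(out) <- names(spec$marginals)
  out
}

# latent MVN with given correlation; PSD matrices handled through a
# pivoted Cholesky fallback so degenerate (comonotone) blocks still sample
latent_normals <- function(n, corr) {
  d <- nrow(corr)
  ch <- tryCatch(chol(corr), error = function(e) {
    es <- eigen(corr, symmetric = TRUE)
    va <- pmax(es$values, 0)
    t(es$vectors %*% diag(sqrt(va), d))
  })
  matrix(rnorm(n * d), n, d) %*% ch
}

marginal_quantile <- function(u, m) {
  switch(m$type,
    pert = qpert(u, m$min, m$mode, m$max),
    normal = {
      lo <- m$lower %||% -Inf
      hi <- m$upper %||% Inf
      plo <- pnorm(lo, m$mean, m$sd)
      phi <- pnorm(hi, m$mean, m$sd)
      qnorm(plo + u * (phi - plo), m$mean, m$sd)
    },
    lognormal = qlnorm(u, m$meanlog, m$sdlog),
    bernoulli = as.numeric(u < m$pos),
    stop(sprintf("unknown marginal type '%s'", m$type), call. = FALSE)
  )
}

# exchangeable correlation matrix
exchangeable_corr <- function(d, rho) {
  m <- matrix(rho, d, d)
  diag(m) <- 1
  m
}
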