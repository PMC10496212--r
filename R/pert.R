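#' The PERT distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the (classical) PERT distribution: a Beta distribution rescaled to
#' `[min, max]` with shape parameters
#' `alpha = 1 + 4 (mode - min) / (max - min)` and
#' `beta  = 1 + 4 (max - mode) / (max - min)`.
#'
#' The PERT distribution is the standard way to turn a three-point
#' (minimum / most likely / maximum) expert estimate into a probability
#' distribution for project costs and durations. Its mean is
#' `(min + 4 mode + max) / 6` and its variance
#' `(mean - min) (max - mean) / 7`. The degenerate case `min == max`
#' is accepted and treated as a point mass.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param min,mode,max the three-point estimate (`min <= mode <= max`).
#' @return `dpert` gives the density, `ppert` the CDF, `qpert` the quantile
#'   function and `rpert` random draws.
#' @examples
#' mean(rpert(1e4, 4, 6, 8))      # close to 6
#' pert_mean(9, 14, 40)           # (9 + 56 + 40) / 6
#' @export
rpert <- function(n, min, mode, max) {
  check_pert(min, mode, max)
  if (min == max) return(rep(min, n))
  sh <- pert_shapes(min, mode, max)
  min + (max - min) * rbeta(n, sh[1], sh[2])
}

#' @rdname rpert
#' @export
dpert <- function(x, min, mode, max) {
  check_pert(min, mode, max)
  if (min == max) return(ifelse(x == min, Inf, 0))
  sh <- pert_shapes(min, mode, max)
  dbeta((x - min) / (max - min), sh[1], sh[2]) / (max - min)
}

#' @rdname rpert
#' @export
ppert <- function(q, min, mode, max) {
  check_pert(min, mode, max)
  if (min == max) return(as.numeric(q >= min))
  sh <- pert_shapes(min, mode, max)
  pbeta((q - min) / (max - min), sh[1], sh[2])
}

#' @rdname rpert
#' @export
qpert <- function(p, min, mode, max) {
  check_pert(min, mode, max)
  if (min == max) return(rep(min, length(p)))
  sh <- pert_shapes(min, mode, max)
  min + (max - min) * qbeta(p, sh[1], sh[2])
}

#' @rdname rpert
#' @export
pert_mean <- function(min, mode, max) (min + 4 * mode + max) / 6

#' @rdname rpert
#' @export
pert_var <- function(min, mode, max) {
  m <- pert_mean(min, mode, max)
  (m - min) * (max - m) / 7
}

pert_shapes <- function(min, mode, max) {
  c(1 + 4 * (mode - min) / (max - min),
    1 + 4 * (max - mode) / (max - min))
}

check_pert <- function(min, mode, max) {
  if (!(min <= mode && mode <= max))
    stop("PERT parameters must satisfy min <= mode <= max", call. = FALSE)
  invisible(NULL)
}
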