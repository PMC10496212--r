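#' Present value of a uniformly distributed cash-flow stream
#'
#' Both functions value a total `amount` accruing uniformly in continuous
#' time over `[t0, t1]` (years from time 0) at annual-effective discount
#' rate `r`, under two conventions:
#'
#' * `discount_uniform_stream()` discounts every instant exactly:
#'   `PV = amount * ((1+r)^-t0 - (1+r)^-t1) / ((t1 - t0) * log(1+r))`,
#'   with the limit `amount` as `r -> 0`.
#' * `discount_annual_stream()` allocates the accrual to calendar-year
#'   buckets `(k-1, k]` and discounts each bucket at its year end,
#'   `(1+r)^-k`. This is the discrete annual end-of-period convention
#'   used by spreadsheet-style valuations; it is the package default
#'   because the engine is calibrated under it.
#'
#' Both handle non-integer endpoints, so phase timelines need not fall
#' on year boundaries. Arguments are vectorized over paths.
#'
#' @param amount total cash amount (same currency unit as the result).
#' @param t0,t1 start and end of the accrual window, years, `t1 > t0 >= 0`.
#' @param r annual discount rate, `r >= 0`.
#' @return present value at time 0.
#' @examples
#' discount_uniform_stream(100, 0, 1, 0.13)  # 94.13
#' discount_annual_stream(100, 0, 1, 0.13)   # 100 / 1.13
#' @export
discount_uniform_stream <- function(amount, t0, t1, r) {
  if (any(t1 <= t0)) stop("need t1 > t0", call. = FALSE)
  if (any(t0 < 0) || any(r < 0)) stop("need t0 >= 0 and r >= 0", call. = FALSE)
  if (all(r == 0)) return(amount + 0 * t0)
  amount * ((1 + r)^(-t0) - (1 + r)^(-t1)) / ((t1 - t0) * log(1 + r))
}

#' @rdname discount_uniform_stream
#' @export
discount_annual_stream <- function(amount, t0, t1, r) {
  if (any(t1 <= t0)) stop("need t1 > t0", call. = FALSE)
  if (any(t0 < 0) || any(r < 0)) stop("need t0 >= 0 and r >= 0", call. = FALSE)
  n <- max(length(amount), length(t0), length(t1))
  amount <- rep_len(amount, n); t0 <- rep_len(t0, n); t1 <- rep_len(t1, n)
  out <- numeric(n)
  for (k in seq_len(ceiling(max(t1)))) {
    ov <- pmin(k, t1) - pmax(k - 1, t0)
    ov[ov < 0] <- 0
    out <- out + amount * ov / (t1 - t0) * (1 + r)^(-k)
  }
  out
}

# convention dispatch used by the engine
pv_stream <- function(amount, t0, t1, r, convention) {
  switch(convention,
         annual = discount_annual_stream(amount, t0, t1, r),
         continuous = discount_uniform_stream(amount, t0, t1, r),
         stop(sprintf("unknown discounting convention '%s'", convention), call. = FALSE))
}

# PV at time 0 of the post-launch revenue stream. Vectorized over paths.
# Revenue year y spans [L + y - 1, L + y]; under the annual convention the
# year's cash flow settles at the year end; a fractional final year earns
# (and settles at) its earned fraction. `atcf_peak` is the after-tax cash
# flow at full peak adoption ($M/year); the ramp scales it per year.
pv_revenue <- function(atcf_peak, ramp, launch, excl, r, convention) {
  n <- max(length(atcf_peak), length(launch), length(excl))
  atcf_peak <- rep_len(atcf_peak, n)
  launch <- rep_len(launch, n); excl <- rep_len(excl, n)
  out <- numeric(n)
  for (y in seq_len(ceiling(max(excl)))) {
    w <- pmin(excl - (y - 1), 1)
    w[w < 0] <- 0
    f <- ramp[min(y, length(ramp))]
    cf <- atcf_peak * f * w
    out <- out + if (convention == "annual") {
      cf * (1 + r)^(-(launch + y - 1 + w))
    } else {
      idx <- w > 0
      add <- numeric(n)
      add[idx] <- discount_uniform_stream(cf[idx], launch[idx] + y - 1,
                                          launch[idx] + y - 1 + w[idx], r)
      add
    }
  }
  out
}
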