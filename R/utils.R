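#' @importFrom stats coef cor fitted median quantile rnorm runif sd setNames
#'   pnorm psignrank p.adjust vcov var prcomp IQR qnorm
#' @importFrom utils head read.csv write.csv
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Sample coefficient of variation; NA for fewer than 2 values or zero mean.
cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (abs(m) < .Machine$double.eps) return(NA_real_)
  sd(x) / m
}

# OLS slope of y on 0-based index, expressed as percent of mean(y) per cycle.
# Requires >= 3 points; the per-trace mean is the natural scale for decrement
# features because it makes the slope invariant to amplitude rescaling.
pct_slope_per_cycle <- function(y) {
  y <- as.numeric(y)
  if (sum(is.finite(y)) < 3L) return(NA_real_)
  k <- seq_along(y) - 1
  ok <- is.finite(y)
  slope <- unname(coef(stats::lm.fit(cbind(1, k[ok]), y[ok]))[2L])
  m <- mean(y[ok])
  if (abs(m) < .Machine$double.eps) return(NA_real_)
  100 * slope / m
}

stop_stimvision <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "stimvision_error")))
}
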