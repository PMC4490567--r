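#' @importFrom rlang .data
#' @importFrom dplyr group_by summarise ungroup arrange mutate filter select
#'   left_join bind_rows n
#' @importFrom tibble tibble as_tibble
NULL

# Mean Earth radius (km) used for every area and distance in the package.
EARTH_RADIUS_KM <- 6371

#' Derive a reproducible stage seed from a master seed
#'
#' Each pipeline stage draws from its own substream so stages can be rerun
#' individually. The substream seed is a a deterministic rolling hash of
#' the master seed and the stage name, folded into the positive 32-bit range.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return An integer seed, always in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 17
  for (b in utf8ToInt(paste0(stage, ":", format(seed, scientific = FALSE)))) {
    # rolling polynomial hash mod 2^31 - 1; stays exact in doubles
    h <- (h * 1009 + b) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Truncated normal draws by inverse-CDF; degenerate sd = 0 returns the mean.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncated normal: mean outside truncation bounds")
    }
    return(rep(mean, n))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Lognormal parameterized by arithmetic mean and coefficient of variation.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  if (!ok_lo || x > upper) {
    stop(sprintf("`%s` = %g out of range", name, x), call. = FALSE)
  }
  invisible(x)
}
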