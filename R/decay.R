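# mRNA half-life estimation from transcription-shutoff (e.g. actinomycin D)
# time courses. Abundances are normalized to time point 0, so the log-linear
# fit goes through the origin; replicates are pooled by fitting all points
# jointly, preserving the error structure.

#' Estimate an mRNA half-life from a decay time course
#'
#' Least-squares fit of `ln(abundance)` against time with the intercept fixed
#' at 0 (the data are t0-normalized); the decay rate is minus the slope and
#' `T1/2 = ln(2) / rate`. A non-positive rate (non-decaying series) gives an
#' infinite half-life with `decaying = FALSE`.
#'
#' @param time hours, >= 3 distinct time points including 0.
#' @param value relative abundances (> 0), normalized to time 0.
#' @param fixed_intercept fit through the origin (default TRUE; set FALSE for
#'   un-normalized input).
#' @return list: `t_half` (hours), `rate` (per hour), `r2`, `decaying`.
#' @export
estimate_half_life <- function(time, value, fixed_intercept = TRUE) {
  if (length(time) != length(value)) stop("time and value must align")
  if (length(unique(time)) < 3) stop("need >= 3 time points")
  if (!any(time == 0)) stop("time course must include t = 0")
  if (any(value <= 0)) stop("abundances must be positive")
  y <- log(value)
  fit <- if (fixed_intercept) stats::lm(y ~ 0 + time) else stats::lm(y ~ time)
  slope <- unname(stats::coef(fit)[["time"]])
  rate <- -slope
  res <- stats::residuals(fit)
  tss <- if (fixed_intercept) sum(y^2) else sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(res^2) / tss
  if (rate <= 0)
    return(list(t_half = Inf, rate = rate, r2 = r2, decaying = FALSE))
  list(t_half = log(2) / rate, rate = rate, r2 = r2, decaying = TRUE)
}

#' Compare two half-lives with a bootstrap confidence interval
#'
#' Point estimate: `T1/2(b) / T1/2(a)`. The percentile CI resamples replicate
#' ids with replacement within each series and refits the pooled regression.
#'
#' @param series_a,series_b data.frames with `time`, `value`, `replicate`.
#' @param n_boot bootstrap rounds (default 1000).
#' @param seed RNG seed (mandatory).
#' @param conf confidence level (default 0.9).
#' @return list: `ratio`, `t_half_a`, `t_half_b`, `ci` (length-2 vector),
#'   `defined` (FALSE when the denominator half-life is infinite).
#' @export
compare_half_lives <- function(series_a, series_b, n_boot = 1000L, seed,
                               conf = 0.9) {
  if (missing(seed)) stop("seed is mandatory")
  fa <- estimate_half_life(series_a$time, series_a$value)
  fb <- estimate_half_life(series_b$time, series_b$value)
  if (!is.finite(fa$t_half))
    return(list(ratio = NA_real_, t_half_a = fa$t_half, t_half_b = fb$t_half,
                ci = c(NA_real_, NA_real_), defined = FALSE))
  ratio <- fb$t_half / fa$t_half
  old_seed <- .preserve_seed()
  on.exit(.restore_seed(old_seed))
  set.seed(seed)
  boot_one <- function(s) {
    reps <- unique(s$replicate)
    pick <- sample(reps, length(reps), replace = TRUE)
    sub <- do.call(rbind, lapply(pick, function(r) s[s$replicate == r, ]))
    estimate_half_life(sub$time, sub$value)$t_half
  }
  ratios <- vapply(seq_len(n_boot), function(b) {
    ta <- boot_one(series_a)
    tb <- boot_one(series_b)
    if (!is.finite(ta)) NA_real_ else tb / ta
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(ratios, c(alpha, 1 - alpha), na.rm = TRUE))
  list(ratio = ratio, t_half_a = fa$t_half, t_half_b = fb$t_half, ci = ci,
       defined = TRUE)
}
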