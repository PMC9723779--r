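# Most-probable-number titer estimation: maximum likelihood under the
# single-hit Poisson model, with log10-scale confidence intervals.

#' Construct an MPN plate
#'
#' One dilution series: per dilution level, the dilution factor applied to
#' the stock, the inoculated volume, wells scored, and wells positive.
#'
#' @param dilution_factor Numeric vector, factors in (0, 1] (1 = undiluted).
#' @param volume_mL Inoculum volume per well (recycled).
#' @param n_wells Wells per dilution level (recycled).
#' @param n_positive Positive wells per level.
#' @return Data frame of class `mpn_plate`.
#' @export
mpn_plate <- function(dilution_factor, volume_mL, n_wells, n_positive) {
  if (length(dilution_factor) < 1)
    stop("at least one dilution level required")
  plate <- data.frame(
    dilution_factor = as.numeric(dilution_factor),
    volume_mL = as.numeric(volume_mL),
    n_wells = as.integer(n_wells),
    n_positive = as.integer(n_positive)
  )
  if (nrow(plate) < 1) stop("at least one dilution level required")
  if (any(plate$dilution_factor <= 0)) stop("dilution factors must be > 0")
  if (any(plate$volume_mL <= 0)) stop("volumes must be > 0")
  if (any(plate$n_positive < 0 | plate$n_positive > plate$n_wells))
    stop("n_positive must satisfy 0 <= n_positive <= n_wells")
  class(plate) <- c("mpn_plate", "data.frame")
  plate
}

#' Read an MPN plate CSV
#'
#' Header: `dilution_factor,volume_mL,n_wells,n_positive`.
#'
#' @param path CSV path.
#' @return An `mpn_plate`.
#' @export
read_mpn_plate <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  mpn_plate(x$dilution_factor, x$volume_mL, x$n_wells, x$n_positive)
}

# Binomial log-likelihood of concentration c (per mL): each well at level j
# positive with probability 1 - exp(-c * d_j * v_j).
mpn_loglik <- function(c_conc, plate) {
  lam <- c_conc * plate$dilution_factor * plate$volume_mL
  # log(1 - exp(-lam)) computed stably
  lp <- ifelse(lam > 1e-8, log1p(-exp(-lam)), log(lam) - lam / 2)
  sum(plate$n_positive * lp - (plate$n_wells - plate$n_positive) * lam)
}

#' Maximum-likelihood MPN titer estimate
#'
#' Maximizes the binomial likelihood with per-well positive probability
#' `1 - exp(-c * dilution * volume)` over `log10(c)` by Brent-style
#' optimization on a wide bracket. The 95% CI is a Wald interval on
#' `log10(c)` from the observed-information curvature, replaced by a
#' profile-likelihood interval when the curvature is degenerate near the
#' bracket boundaries. All-negative plates give a zero estimate with a
#' finite upper bound only; all-positive plates a lower bound only.
#'
#' @param plate An `mpn_plate` (or data frame with the same columns).
#' @param conf_level Confidence level (default 0.95).
#' @param log10_bracket Search bracket for log10 concentration.
#' @param tol Optimizer tolerance in log10(c).
#' @return List: `titer` (per mL), `log10_titer`, `ci_log10` (length-2,
#'   possibly -Inf/Inf at boundaries), `ci` (back-transformed), `status`
#'   (`"interior"`, `"all_negative"`, `"all_positive"`), `loglik`.
#' @export
#' @examples
#' p <- mpn_plate(c(1e-1, 1e-2, 1e-3), 0.1, 5, c(5, 3, 0))
#' estimate_mpn(p)$titer
estimate_mpn <- function(plate, conf_level = 0.95,
                         log10_bracket = c(-6, 12), tol = 1e-6) {
  plate <- mpn_plate(plate$dilution_factor, plate$volume_mL, plate$n_wells,
                     plate$n_positive)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  crit <- stats::qchisq(conf_level, df = 1) / 2
  total_dv <- sum(plate$n_wells * plate$dilution_factor * plate$volume_mL)

  if (all(plate$n_positive == 0)) {
    # likelihood decreasing in c; upper bound where loglik drops by crit
    upper <- stats::uniroot(
      function(l10) mpn_loglik(10^l10, plate) + crit,
      interval = log10_bracket, tol = tol
    )$root
    return(list(titer = 0, log10_titer = -Inf,
                ci_log10 = c(-Inf, upper), ci = c(0, 10^upper),
                status = "all_negative", loglik = 0))
  }
  if (all(plate$n_positive == plate$n_wells)) {
    # likelihood increasing in c; lower bound from the profile
    sup <- 0  # loglik -> 0 as c -> Inf
    lower <- stats::uniroot(
      function(l10) mpn_loglik(10^l10, plate) - (sup - crit),
      interval = log10_bracket, tol = tol
    )$root
    return(list(titer = Inf, log10_titer = Inf,
                ci_log10 = c(lower, Inf), ci = c(10^lower, Inf),
                status = "all_positive", loglik = sup))
  }

  opt <- stats::optimize(function(l10) mpn_loglik(10^l10, plate),
                         interval = log10_bracket, maximum = TRUE, tol = tol)
  l10_hat <- opt$maximum
  ll_hat <- opt$objective

  # observed information in log10(c) by central difference
  h <- 1e-4
  d2 <- (mpn_loglik(10^(l10_hat + h), plate) - 2 * ll_hat +
           mpn_loglik(10^(l10_hat - h), plate)) / h^2
  ci_l10 <- if (is.finite(d2) && d2 < -1e-8) {
    se <- sqrt(-1 / d2)
    l10_hat + c(-z, z) * se
  } else {
    c(NA_real_, NA_real_)
  }
  # profile fallback if Wald failed or escapes the bracket
  if (anyNA(ci_l10) || ci_l10[1] < log10_bracket[1] ||
      ci_l10[2] > log10_bracket[2]) {
    f <- function(l10) mpn_loglik(10^l10, plate) - (ll_hat - crit)
    lo <- tryCatch(
      stats::uniroot(f, c(log10_bracket[1], l10_hat), tol = tol)$root,
      error = function(e) log10_bracket[1])
    hi <- tryCatch(
      stats::uniroot(f, c(l10_hat, log10_bracket[2]), tol = tol)$root,
      error = function(e) log10_bracket[2])
    ci_l10 <- c(lo, hi)
  }

  list(titer = 10^l10_hat, log10_titer = l10_hat, ci_log10 = ci_l10,
       ci = 10^ci_l10, status = "interior", loglik = ll_hat)
}

#' Pool independent dilution series
#'
#' Sums well counts and positives per dilution level across plates sharing
#' the same dilution scheme, for a single pooled ML estimate.
#'
#' @param plates List of `mpn_plate` objects with identical
#'   `(dilution_factor, volume_mL)` schemes.
#' @return A pooled `mpn_plate`.
#' @export
pool_series <- function(plates) {
  if (length(plates) == 0) stop("no plates supplied")
  ref <- plates[[1]]
  for (p in plates[-1]) {
    if (nrow(p) != nrow(ref) ||
        any(p$dilution_factor != ref$dilution_factor) ||
        any(p$volume_mL != ref$volume_mL))
      stop("plates have mismatched dilution schemes")
  }
  mpn_plate(
    ref$dilution_factor, ref$volume_mL,
    Reduce(`+`, lapply(plates, `[[`, "n_wells")),
    Reduce(`+`, lapply(plates, `[[`, "n_positive"))
  )
}
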