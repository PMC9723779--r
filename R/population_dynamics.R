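# Infection statistics (MOI, Poisson infected fraction), predator-prey
# encounter kernels, and the start-vs-end abundance decline test.

#' Multiplicity of infection
#'
#' MOI = phage concentration / mean host concentration across the
#' phage-bearing treatments. With the study inputs (3e7 pfu/mL on hosts at
#' 2.8e7 and 2.9e7 cells/mL) this is 1.1 at one decimal.
#'
#' @param phage_conc Free phage at inoculation, pfu/mL (>= 0).
#' @param host_concs Numeric vector of host concentrations, cells/mL, one per
#'   phage-bearing treatment.
#' @param rounding_decimals Decimals for the reported MOI (default 1).
#' @return List with `moi` (rounded) and `moi_unrounded`.
#' @export
#' @examples
#' compute_moi(3e7, c(2.8e7, 2.9e7))$moi  # 1.1
compute_moi <- function(phage_conc, host_concs, rounding_decimals = 1) {
  if (length(host_concs) == 0) stop("host_concs must be non-empty")
  if (any(host_concs <= 0)) stop("host concentrations must be > 0")
  if (phage_conc < 0) stop("phage_conc must be >= 0")
  moi <- phage_conc / mean(host_concs)
  list(moi = round(moi, rounding_decimals), moi_unrounded = moi)
}

#' Poisson infected fraction
#'
#' Under a Poisson distribution of adsorbed phage per cell with mean MOI, the
#' fraction of cells receiving at least one phage is 1 - exp(-MOI).
#'
#' @param moi Multiplicity of infection (>= 0).
#' @return Fraction in [0, 1).
#' @export
#' @examples
#' infected_fraction_poisson(1.1)  # ~0.667, i.e. 67%
infected_fraction_poisson <- function(moi) {
  if (any(moi < 0)) stop("moi must be >= 0")
  1 - exp(-moi)
}

#' Format a fraction as a whole percentage
#'
#' @param fraction Numeric fraction(s) in [0, 1].
#' @return Character like `"67%"` (rounded to nearest whole percent).
#' @export
percent_label <- function(fraction) {
  sprintf("%d%%", as.integer(round(100 * fraction)))
}

#' Prey:predator ratio denominator
#'
#' Returns prey per predator, rounded to the nearest `round_to` (default
#' 1000, matching ratios reported as e.g. 1:512,000).
#'
#' @param prey_conc Prey cells/mL.
#' @param predator_conc Predator cells/mL (> 0).
#' @param round_to Rounding grain for the denominator.
#' @return List with `ratio` (rounded denominator) and `label` (`"1:R"`).
#' @export
#' @examples
#' predator_prey_ratio(2.2e7, 43)$ratio  # 512000
predator_prey_ratio <- function(prey_conc, predator_conc, round_to = 1000) {
  if (predator_conc == 0) stop("predator_conc must be > 0 (ratio undefined)")
  r <- round(prey_conc / predator_conc / round_to) * round_to
  list(ratio = r, label = sprintf("1:%s", format(r, big.mark = ",",
                                                 scientific = FALSE)))
}

#' Clearance kernel for a cruising predator
#'
#' Volume of water swept per predator per second for a predator cruising at
#' `swim_speed` with effective contact radius `predator_radius +
#' prey_radius`: beta = pi * R^2 * v, converted from um to mL (cm^3).
#'
#' @param predator_radius,prey_radius Radii in micrometres.
#' @param swim_speed Relative swimming speed, um/s.
#' @return Clearance rate beta in mL/s.
#' @export
clearance_kernel_cruising <- function(predator_radius, prey_radius,
                                      swim_speed) {
  if (any(c(predator_radius, prey_radius, swim_speed) < 0))
    stop("kernel inputs must be >= 0")
  contact_cm <- (predator_radius + prey_radius) * 1e-4
  speed_cm_s <- swim_speed * 1e-4
  pi * contact_cm^2 * speed_cm_s  # cm^3/s == mL/s
}

#' Predator-prey encounter rate
#'
#' E = beta * predator * prey, in encounters per mL per second. `beta` may be
#' given directly (calibrated clearance rate) or derived from the cruising
#' kernel via radii and swim speed.
#'
#' @param predator_conc Predator cells/mL.
#' @param prey_conc Prey cells/mL.
#' @param clearance_beta Clearance rate in mL/s; if `NULL`, derived from the
#'   kernel arguments.
#' @param predator_radius,prey_radius,swim_speed Cruising-kernel inputs (um,
#'   um, um/s), used when `clearance_beta` is `NULL`.
#' @return Encounter rate, encounters/mL/s.
#' @export
encounter_rate <- function(predator_conc, prey_conc, clearance_beta = NULL,
                           predator_radius = NULL, prey_radius = NULL,
                           swim_speed = NULL) {
  if (any(c(predator_conc, prey_conc) < 0))
    stop("concentrations must be >= 0")
  if (is.null(clearance_beta)) {
    if (is.null(predator_radius) || is.null(prey_radius) ||
        is.null(swim_speed))
      stop("supply clearance_beta or all of predator_radius, prey_radius, swim_speed")
    clearance_beta <- clearance_kernel_cruising(predator_radius, prey_radius,
                                                swim_speed)
  }
  if (clearance_beta < 0) stop("clearance_beta must be >= 0")
  clearance_beta * predator_conc * prey_conc
}

#' Cumulative fraction of prey encountered
#'
#' Given a constant encounter rate, the fraction of the prey population
#' encountered at least once by time `elapsed_s`: linear accumulation
#' (with-replacement count capped at 1) or exponential
#' (encounter-without-replacement), 1 - exp(-rate * t / prey).
#'
#' @param rate Encounter rate, encounters/mL/s.
#' @param prey_conc Prey cells/mL (> 0).
#' @param elapsed_s Elapsed time in seconds.
#' @param model `"linear"` or `"exponential"`.
#' @return Fraction in [0, 1].
#' @export
cumulative_encountered_fraction <- function(rate, prey_conc, elapsed_s,
                                            model = c("linear", "exponential")) {
  model <- match.arg(model)
  if (prey_conc == 0) stop("prey_conc must be > 0")
  if (any(c(rate, prey_conc, elapsed_s) < 0))
    stop("rate, prey_conc and elapsed_s must be >= 0")
  x <- rate * elapsed_s / prey_conc
  if (model == "linear") pmin(1, x) else 1 - exp(-x)
}

#' Start-vs-end abundance decline test
#'
#' Two-tailed two-sample t-test of replicate abundances at the first vs last
#' sampled timepoint (Welch by default). Direction is the sign of
#' mean(end) - mean(start); a significant negative direction is a decline.
#'
#' @param start_values,end_values Replicate measurements (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use Student's pooled-variance test instead of Welch.
#' @return List: `t`, `p_value`, `significant`, `direction` (-1/0/1),
#'   `mean_change`.
#' @export
abundance_decline_test <- function(start_values, end_values, alpha = 0.05,
                                   var_equal = FALSE) {
  if (length(start_values) < 2 || length(end_values) < 2)
    stop("need >= 2 values per group")
  d <- mean(end_values) - mean(start_values)
  if (stats::var(start_values) == 0 && stats::var(end_values) == 0) {
    if (d == 0)
      return(list(t = 0, p_value = 1, significant = FALSE, direction = 0,
                  mean_change = 0))
    # zero variance, different means: separation is exact
    return(list(t = sign(d) * Inf, p_value = 0, significant = TRUE,
                direction = sign(d), mean_change = d))
  }
  tt <- stats::t.test(end_values, start_values, var.equal = var_equal)
  list(
    t = unname(tt$statistic),
    p_value = tt$p.value,
    significant = tt$p.value < alpha,
    direction = sign(d),
    mean_change = d
  )
}

#' Read an abundance time-series CSV
#'
#' Header: `organism,treatment,replicate,timepoint_h,concentration`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_abundances <- function(path) {
  ab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("organism", "treatment", "replicate", "timepoint_h", "concentration")
  missing <- setdiff(req, names(ab))
  if (length(missing))
    stop("abundance table missing columns: ", paste(missing, collapse = ", "))
  ab
}
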