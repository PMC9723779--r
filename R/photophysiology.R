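# FRRf single-turnover induction curves: blank correction, Fo/Fm extraction,
# Fv/Fm, and per-timepoint treatment comparisons.

#' Construct an FRRf trace
#'
#' A flashlet-resolved fluorescence acquisition. Under the instrument
#' protocol used here the saturation phase is 100 flashlets on a 2-us pitch
#' and the relaxation phase 40 flashlets on a 50-us pitch, repeated over 5
#' sequences; other geometries are accepted.
#'
#' @param flashlets Data frame with columns `sequence`, `flashlet_index`,
#'   `phase` (`"saturation"`/`"relaxation"`), `time_us`, `fluorescence`.
#' @param blank Paired blank: either a scalar fluorescence level or a data
#'   frame with the same flashlet structure (column `fluorescence`).
#' @param sample_id Optional identifier.
#' @return List of class `frrf_trace`.
#' @export
frrf_trace <- function(flashlets, blank = NULL, sample_id = NA_character_) {
  req <- c("sequence", "flashlet_index", "phase", "time_us", "fluorescence")
  if (!all(req %in% names(flashlets)))
    stop("flashlets must have columns: ", paste(req, collapse = ", "))
  if (any(flashlets$fluorescence < 0))
    stop("fluorescence must be >= 0")
  structure(list(flashlets = flashlets, blank = blank, sample_id = sample_id),
            class = "frrf_trace")
}

#' Blank-correct an FRRf trace
#'
#' Subtracts the paired cell-free blank (per-flashlet if a trace, scalar
#' otherwise). Negative results are floored at 0 and counted in a warning.
#'
#' @param trace An `frrf_trace` with a blank.
#' @return Corrected `frrf_trace` (blank set to 0).
#' @export
blank_correct <- function(trace) {
  if (is.null(trace$blank)) stop("trace has no blank")
  b <- if (is.data.frame(trace$blank)) trace$blank$fluorescence
       else trace$blank
  f <- trace$flashlets$fluorescence - b
  n_neg <- sum(f < 0)
  if (n_neg > 0)
    warning(sprintf("%d flashlet(s) below blank floored at 0", n_neg))
  trace$flashlets$fluorescence <- pmax(f, 0)
  trace$blank <- 0
  trace
}

# closure fraction after i absorbed flashlets: C_i = 1 - (1 - sigma)^i
closure_curve <- function(n, sigma) 1 - (1 - sigma)^(seq_len(n) - 1)

#' Fit the single-turnover induction model to a saturation phase
#'
#' Fits the closure recursion C_0 = 0, C_{i+1} = C_i + sigma (1 - C_i)
#' (equivalently C_i = 1 - (1 - sigma)^i) with fluorescence yield
#' F_i = Fo + (Fm - Fo) C_i, by least squares per sequence; parameters are
#' averaged over sequences. This is a reduced single-turnover form without
#' inter-PSII connectivity: each sub-saturating flashlet closes a fixed
#' fraction `sigma` of the still-open reaction centres.
#'
#' @param trace An `frrf_trace`, blank-corrected; saturation phase with
#'   >= 10 flashlets per sequence.
#' @return List of class `photo_params`: `Fo`, `Fm`, `sigma`, `fit_rss`,
#'   `n_sequences`, `converged`.
#' @export
fit_induction <- function(trace) {
  sat <- trace$flashlets[trace$flashlets$phase == "saturation", , drop = FALSE]
  if (nrow(sat) == 0) stop("no saturation-phase flashlets")
  fits <- lapply(split(sat, sat$sequence), fit_induction_one)
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(ok)) stop("induction fit failed to converge in every sequence")
  fits <- fits[ok]
  structure(
    list(
      Fo = mean(vapply(fits, `[[`, numeric(1), "Fo")),
      Fm = mean(vapply(fits, `[[`, numeric(1), "Fm")),
      sigma = mean(vapply(fits, `[[`, numeric(1), "sigma")),
      fit_rss = sum(vapply(fits, `[[`, numeric(1), "rss")),
      n_sequences = length(fits),
      converged = all(ok)
    ),
    class = "photo_params"
  )
}

fit_induction_one <- function(seq_df) {
  seq_df <- seq_df[order(seq_df$flashlet_index), , drop = FALSE]
  y <- seq_df$fluorescence
  n <- length(y)
  if (n < 10) stop("saturation phase needs >= 10 flashlets")
  fo0 <- max(y[1], 1e-8)
  fm0 <- max(max(y), fo0 * 1.01)
  if (stats::sd(y) < .Machine$double.eps^0.5 * max(1, mean(y))) {
    # flat trace: Fm ~ Fo, no closure signal to fit
    return(list(Fo = mean(y), Fm = mean(y), sigma = 0.05, rss = 0,
                converged = TRUE))
  }
  i <- seq_len(n) - 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Fo + (Fm - Fo) * (1 - (1 - sigma)^i),
      start = list(Fo = fo0, Fm = fm0, sigma = 0.05),
      lower = c(0, 0, 1e-6), upper = c(Inf, Inf, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit))
    return(list(Fo = NA_real_, Fm = NA_real_, sigma = NA_real_,
                rss = NA_real_, converged = FALSE))
  cf <- stats::coef(fit)
  list(Fo = unname(cf["Fo"]), Fm = unname(cf["Fm"]),
       sigma = unname(cf["sigma"]),
       rss = sum(stats::resid(fit)^2), converged = TRUE)
}

#' Maximum photochemical efficiency of PSII
#'
#' Fv/Fm = (Fm - Fo) / Fm from dark-adapted minimum and maximum fluorescence
#' yields.
#'
#' @param params A `photo_params` fit, or a list with `Fo` and `Fm`.
#' @return Ratio in [0, 1).
#' @export
#' @examples
#' fv_fm(list(Fo = 0.7, Fm = 1.0))  # 0.30
fv_fm <- function(params) {
  if (params$Fm <= 0) stop("Fm must be > 0")
  if (params$Fo > params$Fm)
    stop("Fo > Fm: failed or inverted fit")
  (params$Fm - params$Fo) / params$Fm
}

#' Compare Fv/Fm between treatments per timepoint
#'
#' Welch two-tailed t-test of each non-baseline treatment against the
#' baseline at every timepoint, with the percent change of replicate means.
#'
#' @param fvfm Data frame with columns `treatment`, `replicate`,
#'   `timepoint_h`, `fvfm`.
#' @param baseline Baseline treatment name (default `"control"`).
#' @param alpha Significance level.
#' @return Data frame: `treatment`, `timepoint_h`, `mean_fvfm`,
#'   `baseline_mean`, `difference`, `percent_change`, `p_value`,
#'   `significant`.
#' @export
compare_fvfm <- function(fvfm, baseline = "control", alpha = 0.05) {
  req <- c("treatment", "replicate", "timepoint_h", "fvfm")
  if (!all(req %in% names(fvfm)))
    stop("fvfm table must have columns: ", paste(req, collapse = ", "))
  if (!baseline %in% fvfm$treatment)
    stop("baseline treatment '", baseline, "' absent from data")
  others <- setdiff(unique(fvfm$treatment), baseline)
  tps <- sort(unique(fvfm$timepoint_h))
  out <- list()
  for (tr in others) {
    for (tp in tps) {
      a <- fvfm$fvfm[fvfm$treatment == tr & fvfm$timepoint_h == tp]
      b <- fvfm$fvfm[fvfm$treatment == baseline & fvfm$timepoint_h == tp]
      if (length(b) < 2)
        stop(sprintf("baseline cell (%s, %g h) has < 2 replicates",
                     baseline, tp))
      if (length(a) < 2) next
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        stats::t.test(a, b)$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        treatment = tr, timepoint_h = tp,
        mean_fvfm = mean(a), baseline_mean = mean(b),
        difference = mean(a) - mean(b),
        percent_change = 100 * (mean(a) - mean(b)) / mean(b),
        p_value = p, significant = p < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read FRRf traces from CSV
#'
#' Header: `sample_id,sequence,flashlet_index,phase,time_us,fluorescence`.
#' An optional blank CSV with the same schema supplies per-sample blanks
#' (matched by `sample_id`, or a single blank applied to all).
#'
#' @param traces_path Trace CSV path.
#' @param blanks_path Optional blank CSV path.
#' @return Named list of `frrf_trace` objects.
#' @export
read_frrf_traces <- function(traces_path, blanks_path = NULL) {
  x <- utils::read.csv(traces_path, stringsAsFactors = FALSE)
  blanks <- if (!is.null(blanks_path))
    utils::read.csv(blanks_path, stringsAsFactors = FALSE)
  out <- lapply(split(x, x$sample_id), function(s) {
    b <- NULL
    if (!is.null(blanks)) {
      b <- if (s$sample_id[1] %in% blanks$sample_id)
        blanks[blanks$sample_id == s$sample_id[1], , drop = FALSE]
      else blanks
    }
    frrf_trace(s[, setdiff(names(s), "sample_id")], blank = b,
               sample_id = s$sample_id[1])
  })
  out
}
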