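# Metabolite differential abundance: detection filtering, log10 transform,
# dual fold-change / BH-FDR significance calls, direction classes, and
# annotation confidence levels, per compartment x treatment x timepoint.

#' Construct a metabolite feature table
#'
#' Raw LC-MS peak heights (features x samples) with per-feature annotation
#' evidence and the compartment (intracellular endometabolome or dissolved
#' exometabolome) they were measured in.
#'
#' @param heights Numeric matrix, features x samples, raw peak heights >= 0;
#'   rownames are feature ids, colnames sample ids.
#' @param samples Sample metadata data frame (`sample_id`, `treatment`,
#'   `replicate`, `timepoint_h`, `compartment`) covering every column.
#' @param annotation Optional data frame: `feature_id`, `name`, `class`,
#'   `rt_match`, `mz_match`, `msms_match`, `ion_mode`.
#' @param compartment `"endo"` or `"exo"`.
#' @return List of class `feature_table`.
#' @export
feature_table <- function(heights, samples, annotation = NULL,
                          compartment = c("endo", "exo")) {
  compartment <- match.arg(compartment)
  if (is.null(rownames(heights)) || is.null(colnames(heights)))
    stop("heights must have feature ids as rownames and sample ids as colnames")
  if (any(heights < 0)) stop("peak heights must be >= 0")
  missing <- setdiff(colnames(heights), samples$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  structure(
    list(heights = heights,
         samples = samples[match(colnames(heights), samples$sample_id), ,
                           drop = FALSE],
         annotation = annotation, compartment = compartment),
    class = "feature_table"
  )
}

#' Detection filter for a comparison group
#'
#' A feature is retained for a given treatment x timepoint group iff its raw
#' peak height is at or above `threshold` in at least `min_replicates`
#' biological replicates of that group. Returns per-group retention flags
#' and an exclusion log naming every dropped feature x group.
#'
#' @param table A `feature_table`.
#' @param threshold Detection threshold on raw peak height (default 10000).
#' @param min_replicates Minimum detected replicates (default 2).
#' @return List: `detected` (logical matrix feature x group, groups labelled
#'   `treatment@timepoint`), `exclusion_log` (data frame `feature_id`,
#'   `treatment`, `timepoint_h`, `n_detected`).
#' @export
detection_filter <- function(table, threshold = 10000, min_replicates = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  sm <- table$samples
  groups <- unique(sm[, c("treatment", "timepoint_h")])
  groups <- groups[order(groups$treatment, groups$timepoint_h), , drop = FALSE]
  glab <- paste0(groups$treatment, "@", groups$timepoint_h)
  det <- matrix(FALSE, nrow(table$heights), nrow(groups),
                dimnames = list(rownames(table$heights), glab))
  excl <- list()
  for (g in seq_len(nrow(groups))) {
    cols <- sm$sample_id[sm$treatment == groups$treatment[g] &
                           sm$timepoint_h == groups$timepoint_h[g]]
    n_det <- rowSums(table$heights[, cols, drop = FALSE] >= threshold)
    det[, g] <- n_det >= min_replicates
    dropped <- which(!det[, g])
    if (length(dropped))
      excl[[length(excl) + 1]] <- data.frame(
        feature_id = rownames(table$heights)[dropped],
        treatment = groups$treatment[g],
        timepoint_h = groups$timepoint_h[g],
        n_detected = unname(n_det[dropped]),
        stringsAsFactors = FALSE
      )
  }
  log <- if (length(excl)) do.call(rbind, excl)
         else data.frame(feature_id = character(), treatment = character(),
                         timepoint_h = numeric(), n_detected = integer(),
                         stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(detected = det, exclusion_log = log)
}

#' Log10-transform peak heights
#'
#' Maps raw heights to the log10 analysis scale. Cells below the detection
#' threshold are handled per `zero_policy`: `"impute_half"` (default;
#' impute threshold/2 before log), `"impute_threshold"`, or `"drop"` (NA).
#'
#' @param table A `feature_table`.
#' @param threshold Detection threshold (default 10000).
#' @param zero_policy Sub-threshold handling.
#' @return Numeric matrix of log10 heights, same dimnames as the input.
#' @export
log10_transform <- function(table, threshold = 10000,
                            zero_policy = c("impute_half", "impute_threshold",
                                            "drop")) {
  zero_policy <- match.arg(zero_policy)
  h <- table$heights
  if (any(h < 0)) stop("peak heights must be >= 0")
  sub <- h < threshold
  h[sub] <- switch(zero_policy,
                   impute_half = threshold / 2,
                   impute_threshold = threshold,
                   drop = NA_real_)
  log10(h)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p values in [0, 1].
#' @return Adjusted values in the input order, monotone, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Time-matched metabolite differential abundance
#'
#' For one treatment vs the control at one timepoint:
#' `log10_fc = mean(log10 treatment) - mean(log10 control)` over replicates;
#' p from a two-tailed Welch t-test on log10 values; BH adjustment across
#' all retained features within the (treatment, timepoint, compartment)
#' comparison family; significant iff `|log10_fc| >= fc_threshold` (boundary
#' inclusive) and `fdr <= fdr_threshold`. Features failing the detection
#' filter in either arm are excluded from the family.
#'
#' @param table A `feature_table`.
#' @param treatment,control Treatment names.
#' @param timepoint_h Timepoint to compare at.
#' @param fc_threshold Minimum |log10 fold change| (default 0.1, about a
#'   25% change on the raw scale).
#' @param fdr_threshold BH FDR ceiling (default 0.05).
#' @param detection_threshold,min_replicates Passed to [detection_filter()].
#' @param zero_policy Passed to [log10_transform()].
#' @return Data frame of differential records ordered by `feature_id`:
#'   `feature_id`, `treatment`, `timepoint_h`, `log10_fc`, `p_value`, `fdr`,
#'   `significant`, `direction`, `n_detected_treatment`,
#'   `n_detected_control`.
#' @export
differential_abundance <- function(table, treatment, control = "control",
                                   timepoint_h,
                                   fc_threshold = 0.1, fdr_threshold = 0.05,
                                   detection_threshold = 10000,
                                   min_replicates = 2,
                                   zero_policy = "impute_half") {
  sm <- table$samples
  tcols <- sm$sample_id[sm$treatment == treatment &
                          sm$timepoint_h == timepoint_h]
  ccols <- sm$sample_id[sm$treatment == control &
                          sm$timepoint_h == timepoint_h]
  if (length(tcols) < 2 || length(ccols) < 2)
    stop("need >= 2 replicates per arm")

  flt <- detection_filter(table, detection_threshold, min_replicates)
  gt <- paste0(treatment, "@", timepoint_h)
  gc <- paste0(control, "@", timepoint_h)
  keep <- flt$detected[, gt] & flt$detected[, gc]
  feats <- sort(rownames(table$heights)[keep])
  if (length(feats) == 0) {
    warning("no features retained in both arms")
    return(data.frame(feature_id = character(), treatment = character(),
                      timepoint_h = numeric(), log10_fc = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), direction = character(),
                      n_detected_treatment = integer(),
                      n_detected_control = integer(),
                      stringsAsFactors = FALSE))
  }

  lg <- log10_transform(table, detection_threshold, zero_policy)
  res <- lapply(feats, function(f) {
    a <- lg[f, tcols]
    b <- lg[f, ccols]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    fc <- mean(a) - mean(b)
    p <- if (length(a) < 2 || length(b) < 2) NA_real_
    else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (fc == 0) 1 else 0
    } else stats::t.test(a, b)$p.value
    data.frame(
      feature_id = f, treatment = treatment, timepoint_h = timepoint_h,
      log10_fc = fc, p_value = p,
      n_detected_treatment = sum(table$heights[f, tcols] >=
                                   detection_threshold),
      n_detected_control = sum(table$heights[f, ccols] >=
                                 detection_threshold),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- !is.na(res$fdr) &
    abs(res$log10_fc) >= fc_threshold & res$fdr <= fdr_threshold
  res$direction <- ifelse(res$log10_fc > 0, "enriched", "depleted")
  res[, c("feature_id", "treatment", "timepoint_h", "log10_fc", "p_value",
          "fdr", "significant", "direction", "n_detected_treatment",
          "n_detected_control")]
}

#' Run the metabolite differential procedure across all timepoints
#'
#' Applies [differential_abundance()] at every design timepoint for one
#' treatment-vs-control comparison and binds the records.
#'
#' @inheritParams differential_abundance
#' @param timepoints_h Timepoints to compare at (default: all shared).
#' @return Bound data frame of differential records.
#' @export
differential_abundance_timecourse <- function(table, treatment,
                                              control = "control",
                                              timepoints_h = NULL, ...) {
  if (is.null(timepoints_h))
    timepoints_h <- sort(unique(
      table$samples$timepoint_h[table$samples$treatment == treatment]))
  out <- lapply(timepoints_h, function(tp)
    differential_abundance(table, treatment, control, tp, ...))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotation confidence level
#'
#' Level 1 when all three identification criteria (retention-time match,
#' m/z match, MS/MS match) are met; level 2 when exactly two are; otherwise
#' the feature is unidentified ("Other").
#'
#' @param rt_match,mz_match,msms_match Logical flags (vectorized).
#' @return Character vector: `"level_1"`, `"level_2"`, or `"unidentified"`.
#' @export
annotation_confidence <- function(rt_match, mz_match, msms_match) {
  n <- as.integer(rt_match) + as.integer(mz_match) + as.integer(msms_match)
  c("unidentified", "unidentified", "level_2", "level_1")[n + 1]
}

#' Percent change implied by a log10 fold-change threshold
#'
#' @param fc_threshold Threshold on |log10 FC|.
#' @return Percent change on the raw scale, `(10^threshold - 1) * 100`.
#' @export
fc_threshold_percent <- function(fc_threshold) {
  (10^fc_threshold - 1) * 100
}

#' Read a long-format feature table CSV
#'
#' Header: `feature_id,sample_id,peak_height`; optional annotation CSV with
#' header `feature_id,name,class,rt_match,mz_match,msms_match,ion_mode`.
#'
#' @param table_path Long CSV path.
#' @param samples Sample metadata data frame.
#' @param annotation_path Optional annotation CSV path.
#' @param compartment `"endo"` or `"exo"`.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(table_path, samples, annotation_path = NULL,
                               compartment = "endo") {
  x <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  req <- c("feature_id", "sample_id", "peak_height")
  if (!all(req %in% names(x)))
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  h <- stats::xtabs(peak_height ~ feature_id + sample_id, data = x)
  h <- matrix(h, nrow(h), ncol(h),
              dimnames = unname(lapply(dimnames(h), identity)))
  ann <- if (!is.null(annotation_path))
    utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  feature_table(h, samples, ann, compartment)
}
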