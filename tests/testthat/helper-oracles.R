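# Independent brute-force oracles: textbook formulas coded without calling
# the implementation or the base helpers it wraps (p.adjust, t.test).

# Benjamini-Hochberg step-up, by the definitional formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Two-tailed Welch t-test p value by the textbook formula.
oracle_welch_p <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Full metabolite differential procedure as an explicit loop: detection
# rule, log10 with threshold/2 imputation, Welch t, step-up BH, dual
# threshold. `heights` features x samples; treat/ctrl are column indices.
oracle_metabo_diff <- function(heights, treat_cols, ctrl_cols,
                               threshold = 10000, min_reps = 2,
                               fc_thr = 0.1, fdr_thr = 0.05) {
  feats <- sort(rownames(heights))
  keep <- character(0)
  for (f in feats) {
    if (sum(heights[f, treat_cols] >= threshold) >= min_reps &&
        sum(heights[f, ctrl_cols] >= threshold) >= min_reps)
      keep <- c(keep, f)
  }
  if (!length(keep)) return(NULL)
  lg <- function(x) log10(ifelse(x < threshold, threshold / 2, x))
  fc <- p <- numeric(length(keep))
  for (i in seq_along(keep)) {
    a <- lg(heights[keep[i], treat_cols])
    b <- lg(heights[keep[i], ctrl_cols])
    fc[i] <- mean(a) - mean(b)
    p[i] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (fc[i] == 0) 1 else 0
    } else oracle_welch_p(a, b)
  }
  fdr <- oracle_bh(p)
  data.frame(feature_id = keep, log10_fc = fc, p_value = p, fdr = fdr,
             significant = abs(fc) >= fc_thr & fdr <= fdr_thr,
             stringsAsFactors = FALSE)
}

# Venn region counts by direct membership enumeration over the union.
oracle_venn <- function(sets) {
  labels <- sort(names(sets))
  universe <- unique(unlist(sets))
  combos <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  for (e in universe) {
    inset <- labels[vapply(labels, function(l) e %in% sets[[l]], logical(1))]
    counts[paste(inset, collapse = "&")] <-
      counts[paste(inset, collapse = "&")] + 1L
  }
  counts
}

# Small two-arm feature table fixture: `spec` is a list of per-feature
# height vectors, one row per feature, covering 4 treatment + 4 control
# replicates at a single timepoint.
toy_feature_table <- function(spec, timepoint_h = 6) {
  ids <- names(spec)
  h <- do.call(rbind, spec)
  rownames(h) <- ids
  samples <- data.frame(
    sample_id = c(paste0("t", 1:4), paste0("c", 1:4)),
    treatment = rep(c("phage", "control"), each = 4),
    replicate = rep(1:4, 2),
    timepoint_h = timepoint_h,
    compartment = "endo",
    stringsAsFactors = FALSE
  )
  colnames(h) <- samples$sample_id
  feature_table(h, samples, compartment = "endo")
}

# Noiseless single-sequence saturation trace from closure-model parameters.
toy_trace <- function(Fo, Fm, sigma, n = 100, blank = 0) {
  i <- 0:(n - 1)
  fl <- data.frame(
    sequence = 1L, flashlet_index = seq_len(n), phase = "saturation",
    time_us = i * 2, fluorescence = Fo + (Fm - Fo) * (1 - (1 - sigma)^i),
    stringsAsFactors = FALSE
  )
  frrf_trace(fl, blank = blank)
}
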