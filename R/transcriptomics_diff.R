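# Time-matched treatment-vs-control differential expression on log2RPKM,
# phage temporal-class assignment, and functional-category aFC summaries.

#' Construct an expression matrix
#'
#' Gene x sample read counts with per-gene lengths, host/phage origin and
#' optional functional-category labels.
#'
#' @param counts Integer matrix, genes x samples; rownames gene ids,
#'   colnames sample ids.
#' @param gene_info Data frame: `gene_id`, `length_bp`, `origin`
#'   (`"host"`/`"phage"`), optional `category`.
#' @param samples Sample metadata data frame covering every column.
#' @return List of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_info, samples) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  gi <- gene_info[match(rownames(counts), gene_info$gene_id), , drop = FALSE]
  if (anyNA(gi$gene_id))
    stop("gene_info missing entries for some genes")
  if (any(gi$length_bp <= 0)) stop("gene lengths must be > 0")
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  structure(
    list(counts = counts, gene_info = gi,
         samples = samples[match(colnames(counts), samples$sample_id), ,
                           drop = FALSE]),
    class = "expression_matrix"
  )
}

#' RPKM and log2RPKM
#'
#' RPKM = count * 1e9 / (library_size * length_bp), with library size the
#' total counts of each sample column; log2RPKM = log2(RPKM + pseudocount).
#'
#' @param mat An `expression_matrix`.
#' @param pseudocount Added before log2 (default 1).
#' @return List with matrices `rpkm` and `log2rpkm`.
#' @export
rpkm <- function(mat, pseudocount = 1) {
  lib <- colSums(mat$counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(mat$counts)[lib == 0], collapse = ", "))
  r <- sweep(mat$counts * 1e9 / mat$gene_info$length_bp, 2, lib, "/")
  list(rpkm = r, log2rpkm = log2(r + pseudocount))
}

#' Time-matched differential expression
#'
#' Per gene at each timepoint: `log2_fc = mean(log2RPKM treatment) -
#' mean(log2RPKM control)` over replicates; two-tailed Welch t-test on
#' log2RPKM; BH across genes within each (treatment, timepoint) family;
#' significant iff `|log2_fc| >= fc_threshold` and `fdr <= fdr_threshold`.
#'
#' @param mat An `expression_matrix`.
#' @param treatment,control Treatment names.
#' @param timepoints_h Timepoints (default: all with both arms present).
#' @param fc_threshold Minimum |log2 FC| (default 1).
#' @param fdr_threshold BH FDR ceiling (default 0.05).
#' @param pseudocount Passed to [rpkm()].
#' @return Data frame ordered by timepoint then `gene_id`: `gene_id`,
#'   `treatment`, `timepoint_h`, `log2_fc`, `p_value`, `fdr`, `significant`,
#'   `direction` (`"over"`/`"under"`).
#' @export
de_per_timepoint <- function(mat, treatment, control = "control",
                             timepoints_h = NULL, fc_threshold = 1,
                             fdr_threshold = 0.05, pseudocount = 1) {
  sm <- mat$samples
  if (is.null(timepoints_h)) {
    tt <- sort(unique(sm$timepoint_h[sm$treatment == treatment]))
    tc <- sort(unique(sm$timepoint_h[sm$treatment == control]))
    timepoints_h <- intersect(tt, tc)
  }
  lg <- rpkm(mat, pseudocount)$log2rpkm
  genes <- sort(rownames(mat$counts))
  out <- list()
  for (tp in timepoints_h) {
    tcols <- sm$sample_id[sm$treatment == treatment & sm$timepoint_h == tp]
    ccols <- sm$sample_id[sm$treatment == control & sm$timepoint_h == tp]
    if (length(tcols) < 2 || length(ccols) < 2) {
      warning(sprintf("timepoint %g h skipped: < 2 replicates in an arm", tp))
      next
    }
    fc <- rowMeans(lg[genes, tcols, drop = FALSE]) -
      rowMeans(lg[genes, ccols, drop = FALSE])
    p <- vapply(genes, function(g) {
      a <- lg[g, tcols]; b <- lg[g, ccols]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else stats::t.test(a, b)$p.value
    }, numeric(1))
    fdr <- bh_adjust(p)
    out[[length(out) + 1]] <- data.frame(
      gene_id = genes, treatment = treatment, timepoint_h = tp,
      log2_fc = unname(fc), p_value = unname(p), fdr = unname(fdr),
      significant = abs(fc) >= fc_threshold & fdr <= fdr_threshold,
      direction = ifelse(fc > 0, "over", "under"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation of expression between two conditions
#'
#' Replicate-averaged log2RPKM of the gene subset is paired gene x timepoint
#' between the two conditions; returns the overall Pearson r plus a
#' per-timepoint r vector.
#'
#' @param mat An `expression_matrix`.
#' @param condition_a,condition_b Treatment names.
#' @param gene_subset Gene ids (default: phage genes).
#' @param pseudocount Passed to [rpkm()].
#' @return List: `r` (overall), `r_by_timepoint` (named vector; NA where
#'   variance is zero, flagged in `degenerate_timepoints`).
#' @export
correlate_conditions <- function(mat, condition_a, condition_b,
                                 gene_subset = NULL, pseudocount = 1) {
  if (is.null(gene_subset))
    gene_subset <- mat$gene_info$gene_id[mat$gene_info$origin == "phage"]
  lg <- rpkm(mat, pseudocount)$log2rpkm[gene_subset, , drop = FALSE]
  sm <- mat$samples
  tps <- sort(intersect(unique(sm$timepoint_h[sm$treatment == condition_a]),
                        unique(sm$timepoint_h[sm$treatment == condition_b])))
  avg <- function(cond) vapply(tps, function(tp) {
    cols <- sm$sample_id[sm$treatment == cond & sm$timepoint_h == tp]
    rowMeans(lg[, cols, drop = FALSE])
  }, numeric(length(gene_subset)))
  a <- avg(condition_a); b <- avg(condition_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a condition: correlation undefined")
  r_tp <- vapply(seq_along(tps), function(j) {
    if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) NA_real_
    else stats::cor(a[, j], b[, j])
  }, numeric(1))
  names(r_tp) <- tps
  list(r = stats::cor(as.vector(a), as.vector(b)), r_by_timepoint = r_tp,
       degenerate_timepoints = tps[is.na(r_tp)])
}

#' Standardize expression across timepoints
#'
#' Per gene: replicate-averaged log2RPKM time series, centred on its
#' across-timepoint mean and scaled by its across-timepoint sd. Constant
#' genes become all-zero rows and are flagged.
#'
#' @param mat An `expression_matrix`.
#' @param condition Treatment name whose samples to use.
#' @param gene_subset Gene ids (default: phage genes).
#' @param pseudocount Passed to [rpkm()].
#' @return List: `z` (gene x timepoint matrix), `constant_genes`.
#' @export
standardize_expression <- function(mat, condition, gene_subset = NULL,
                                   pseudocount = 1) {
  if (is.null(gene_subset))
    gene_subset <- mat$gene_info$gene_id[mat$gene_info$origin == "phage"]
  lg <- rpkm(mat, pseudocount)$log2rpkm[gene_subset, , drop = FALSE]
  sm <- mat$samples
  tps <- sort(unique(sm$timepoint_h[sm$treatment == condition]))
  if (length(tps) < 2) stop("need >= 2 timepoints to standardize")
  avg <- vapply(tps, function(tp) {
    cols <- sm$sample_id[sm$treatment == condition & sm$timepoint_h == tp]
    rowMeans(lg[, cols, drop = FALSE])
  }, numeric(length(gene_subset)))
  avg <- matrix(avg, nrow = length(gene_subset),
                dimnames = list(gene_subset, tps))
  mu <- rowMeans(avg)
  sdv <- apply(avg, 1, stats::sd)
  const <- sdv == 0
  z <- (avg - mu) / ifelse(const, 1, sdv)
  z[const, ] <- 0
  list(z = z, constant_genes = gene_subset[const])
}

#' Assign phage temporal expression classes
#'
#' Classifies each gene as early / middle / late by the tercile of the first
#' infection-cycle window containing its peak standardized expression
#' (window default 2-8 h, matching a ~6-8 h latent period). Ties go to the
#' earlier timepoint. When a second condition is supplied, genes whose class
#' differs between conditions are flagged as temporal-dynamics switches.
#'
#' @param z Standardized gene x timepoint matrix (colnames = hours), as from
#'   [standardize_expression()].
#' @param z_other Optional matrix for the second condition (same genes).
#' @param window_h Length-2 infection-cycle window in hours.
#' @return Data frame: `gene_id`, `class`, `peak_h`, and with `z_other`:
#'   `class_other`, `switch`.
#' @export
assign_temporal_class <- function(z, z_other = NULL, window_h = c(2, 8)) {
  tps <- as.numeric(colnames(z))
  win <- tps[tps >= window_h[1] & tps <= window_h[2]]
  if (length(win) == 0)
    stop("window outside sampled timepoints")
  classify <- function(zz) {
    sub <- zz[, as.character(win), drop = FALSE]
    peak <- win[apply(sub, 1, which.max)]  # which.max takes the first tie
    brk <- window_h[1] + diff(window_h) * c(1, 2) / 3
    cls <- ifelse(peak <= brk[1], "early",
                  ifelse(peak <= brk[2], "middle", "late"))
    data.frame(gene_id = rownames(zz), class = cls, peak_h = peak,
               stringsAsFactors = FALSE)
  }
  out <- classify(z)
  if (!is.null(z_other)) {
    other <- classify(z_other[rownames(z), , drop = FALSE])
    out$class_other <- other$class
    out$switch <- out$class != out$class_other
  }
  rownames(out) <- NULL
  out
}

#' Functional-category average fold change
#'
#' For significant genes in each category at one timepoint: the gene count
#' and the average linear fold change, aFC = mean(2^|log2_fc|), with the
#' dominant regulation direction reported separately. Categories with no
#' significant genes are omitted.
#'
#' @param de_records Data frame from [de_per_timepoint()].
#' @param category_map Data frame `gene_id`, `category`.
#' @param timepoint_h Timepoint to summarize at.
#' @return Data frame: `category`, `n_genes`, `aFC`, `n_over`, `n_under`.
#' @export
category_summary <- function(de_records, category_map, timepoint_h) {
  rec <- de_records[de_records$timepoint_h == timepoint_h &
                      de_records$significant, , drop = FALSE]
  if (nrow(rec) == 0)
    return(data.frame(category = character(), n_genes = integer(),
                      aFC = numeric(), n_over = integer(),
                      n_under = integer(), stringsAsFactors = FALSE))
  rec$category <- category_map$category[match(rec$gene_id,
                                              category_map$gene_id)]
  rec <- rec[!is.na(rec$category), , drop = FALSE]
  out <- do.call(rbind, lapply(split(rec, rec$category), function(s) {
    data.frame(
      category = s$category[1],
      n_genes = nrow(s),
      aFC = mean(2^abs(s$log2_fc)),
      n_over = sum(s$direction == "over"),
      n_under = sum(s$direction == "under"),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold increase in the number of DE genes
#'
#' Ratio of differentially expressed gene counts between two treatments,
#' rounded to one decimal (e.g. 216 vs 48 -> 4.5). A zero denominator (as
#' for a treatment with no DE genes) is flagged undefined.
#'
#' @param n_treatment,n_reference DE gene counts.
#' @return List: `ratio` (NA when undefined), `defined`.
#' @export
fold_increase_in_de <- function(n_treatment, n_reference) {
  if (n_reference == 0)
    return(list(ratio = NA_real_, defined = FALSE))
  list(ratio = round(n_treatment / n_reference, 1), defined = TRUE)
}

#' Read a counts TSV and gene metadata TSV
#'
#' Counts: `gene_id` column then one column per sample id. Gene metadata:
#' `gene_id,length_bp,origin[,category]`.
#'
#' @param counts_path,genes_path TSV paths.
#' @param samples Sample metadata data frame.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(counts_path, genes_path, samples) {
  x <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  counts <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(counts) <- x$gene_id
  gi <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  expression_matrix(counts, gi, samples)
}
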