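# Cross-treatment set partitioning (Venn counts), heatmap-matrix export,
# run orchestration, and plain-text writers with lossless round-trips.

#' Exclusive Venn region counts for 2 or 3 significant sets
#'
#' Partitions the union of the sets into its 2^n - 1 exclusive regions.
#' Region labels are the sorted member-set labels joined with `&`.
#'
#' @param sets Named list of 2 or 3 character vectors (entity ids);
#'   names must be unique.
#' @return Named integer vector of exclusive region counts; sums to the
#'   union size.
#' @export
#' @examples
#' venn_partition(list(A = c("a", "b"), B = c("b", "c")))
venn_partition <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3)
    stop("venn_partition takes 2 or 3 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == ""))
    stop("sets must have unique non-empty labels")
  sets <- lapply(sets, unique)
  labels <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = length(sets),
                       dimnames = list(universe, labels))
  region_of <- apply(membership, 1, function(m)
    paste(sort(labels[m]), collapse = "&"))
  # all 2^n - 1 region labels, including empty ones
  combos <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(sort(labels), k, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(region_of)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Export a differential-record heatmap matrix
#'
#' Pivots records of one treatment comparison to an entity x timepoint
#' matrix of fold changes; non-significant cells become NA when masked
#' (the "gray cells" of a significance heatmap). Rows are ordered by
#' descending count of significant timepoints, then id.
#'
#' @param records Data frame of differential records (metabolite or gene)
#'   with an id column (`feature_id` or `gene_id`), `timepoint_h`,
#'   `significant`, and the value column.
#' @param value `"log10_fc"` or `"log2_fc"`; must match the records.
#' @param mask_nonsignificant Emit NA for non-significant cells.
#' @param path Optional TSV output path (rows = entities, first column
#'   `entity_id`).
#' @return The matrix, invisibly when written to `path`.
#' @export
export_heatmap_matrix <- function(records, value = c("log10_fc", "log2_fc"),
                                  mask_nonsignificant = TRUE, path = NULL) {
  value <- match.arg(value)
  if (!value %in% names(records))
    stop("records do not carry a '", value, "' column (mixed value scales?)")
  other <- setdiff(c("log10_fc", "log2_fc"), value)
  if (other %in% names(records))
    stop("records carry both fold-change scales; export one at a time")
  idcol <- intersect(c("feature_id", "gene_id"), names(records))[1]
  if (is.na(idcol)) stop("records need a feature_id or gene_id column")
  if (length(unique(records$treatment)) > 1)
    stop("records must share one treatment comparison")
  tps <- sort(unique(records$timepoint_h))
  nsig <- tapply(records$significant, records[[idcol]], sum)
  ids <- names(sort(nsig, decreasing = TRUE))
  ids <- ids[order(-nsig[ids], ids)]
  m <- matrix(NA_real_, length(ids), length(tps),
              dimnames = list(ids, tps))
  vals <- records[[value]]
  if (mask_nonsignificant) vals[!records$significant] <- NA_real_
  m[cbind(match(records[[idcol]], ids),
          match(records$timepoint_h, tps))] <- vals
  if (!is.null(path)) {
    out <- data.frame(entity_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write_table(out, path)
    return(invisible(m))
  }
  m
}

#' Write a data frame as TSV (lossless float round-trip)
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) ifelse(is.na(v), NA,
                                              format(v, digits = 15,
                                                     scientific = TRUE,
                                                     trim = TRUE)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates every stage against generated inputs: design validation,
#' abundance simulation and decline tests, MOI / infected fraction /
#' predator:prey ratios, FRRf fitting and Fv/Fm comparison, metabolite
#' differential abundance per compartment, differential expression, phage
#' temporal classes, and Venn partitions of the significant sets. Returns
#' all stage outputs with a reproducibility manifest.
#'
#' @param config A `simulation_config`.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV and the manifest as YAML.
#' @param verbose Log stage progress to stderr.
#' @return List of class `virocell_run`: `manifest`, `violations`,
#'   `abundances`, `decline`, `infection`, `fvfm`, `fvfm_comparison`,
#'   `metabo_endo`, `metabo_exo`, `de_records`, `phage_classes`, `venn`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  log_stage <- function(...) if (verbose) message("[virocell] ", ...)
  d <- config$design

  log_stage("validate: design structure")
  violations <- validate_design(d, enumerate_samples(d, "rna"))
  if (nrow(violations) > 0)
    stop("pipeline aborted at stage 'validate': design incomplete")

  log_stage("simulate: abundances, counts, features, FRRf")
  ab <- generate_abundances(config)
  cnt <- generate_counts(config)
  endo <- generate_feature_table(config, "endo")
  exo <- generate_feature_table(config, "exo")
  frrf <- generate_frrf(config)

  log_stage("popdyn: infection statistics and decline tests")
  conc <- d$start_concentrations
  moi <- compute_moi(conc$phage[["phage"]],
                     unname(d$inoculation_host_concs))
  infection <- list(
    moi = moi$moi,
    infected_fraction = infected_fraction_poisson(moi$moi),
    ratio_protist = predator_prey_ratio(conc$protist[["host"]],
                                        conc$protist[["protist"]])$ratio,
    ratio_phage_protist = predator_prey_ratio(
      conc$phage_protist[["host"]], conc$phage_protist[["protist"]])$ratio
  )
  tps <- d$timepoints_h
  decline <- do.call(rbind, lapply(treatment_names(d), function(tr) {
    h <- ab[ab$organism == "host" & ab$treatment == tr, ]
    res <- abundance_decline_test(
      h$concentration[h$timepoint_h == min(tps)],
      h$concentration[h$timepoint_h == max(tps)])
    data.frame(treatment = tr, t = res$t, p_value = res$p_value,
               significant = res$significant, direction = res$direction,
               stringsAsFactors = FALSE)
  }))

  log_stage("physiology: induction fits and Fv/Fm comparisons")
  fvfm_tab <- do.call(rbind, lapply(names(frrf$traces), function(id) {
    tr <- blank_correct(frrf$traces[[id]])
    fit <- fit_induction(tr)
    meta <- frrf$truth[frrf$truth$sample_id == id, ]
    data.frame(sample_id = id, treatment = meta$treatment,
               replicate = meta$replicate, timepoint_h = meta$timepoint_h,
               fvfm = fv_fm(fit), stringsAsFactors = FALSE)
  }))
  fvfm_cmp <- compare_fvfm(fvfm_tab, baseline = "control")

  log_stage("metabodiff: endo and exo compartments")
  non_control <- setdiff(treatment_names(d), "control")
  metabo <- lapply(list(endo = endo$table, exo = exo$table), function(tab) {
    res <- lapply(non_control, function(tr)
      differential_abundance_timecourse(
        tab, tr, "control",
        detection_threshold = config$detection_threshold))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })

  log_stage("rnadiff: differential expression and phage temporal classes")
  de <- do.call(rbind, lapply(non_control, function(tr)
    de_per_timepoint(cnt$matrix, tr, "control")))
  rownames(de) <- NULL
  phage_genes <- cnt$matrix$gene_info$gene_id[
    cnt$matrix$gene_info$origin == "phage"]
  phage_classes <- if (length(phage_genes) >= 2) {
    z_a <- standardize_expression(cnt$matrix, "phage", phage_genes)$z
    z_b <- standardize_expression(cnt$matrix, "phage_protist", phage_genes)$z
    assign_temporal_class(z_a, z_b,
                          window_h = c(min(tps), d$latent_period_h[2]))
  }

  log_stage("report: venn partitions")
  sig_sets <- function(records, idcol) {
    lapply(stats::setNames(non_control, non_control), function(tr) {
      r <- records[records$treatment == tr & records$significant, ]
      unique(r[[idcol]])
    })
  }
  venn <- list(
    endo = venn_partition(sig_sets(metabo$endo, "feature_id")),
    exo = venn_partition(sig_sets(metabo$exo, "feature_id")),
    genes = venn_partition(sig_sets(de, "gene_id"))
  )

  manifest <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    n_features = config$n_features,
    n_samples_rna = ncol(cnt$matrix$counts),
    config_fingerprint = config_fingerprint(config),
    stages = c("validate", "simulate", "popdyn", "physiology",
               "metabodiff", "rnadiff", "report")
  )

  run <- structure(
    list(manifest = manifest, violations = violations, abundances = ab,
         decline = decline, infection = infection, fvfm = fvfm_tab,
         fvfm_comparison = fvfm_cmp, metabo_endo = metabo$endo,
         metabo_exo = metabo$exo, de_records = de,
         phage_classes = phage_classes, venn = venn,
         ledgers = list(counts = cnt$ledger, endo = endo$ledger,
                        exo = exo$ledger)),
    class = "virocell_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ab, file.path(out_dir, "abundances.tsv"))
    write_table(decline, file.path(out_dir, "decline_tests.tsv"))
    write_table(fvfm_tab, file.path(out_dir, "fvfm.tsv"))
    write_table(fvfm_cmp, file.path(out_dir, "fvfm_comparison.tsv"))
    write_table(metabo$endo, file.path(out_dir, "metabo_endo.tsv"))
    write_table(metabo$exo, file.path(out_dir, "metabo_exo.tsv"))
    write_table(de, file.path(out_dir, "de_records.tsv"))
    if (!is.null(phage_classes))
      write_table(phage_classes, file.path(out_dir, "phage_classes.tsv"))
    yaml::write_yaml(c(manifest,
                       list(venn = lapply(venn, as.list),
                            infection = infection)),
                     file.path(out_dir, "manifest.yaml"))
  }
  run
}

# Stable fingerprint of a config: md5 of its canonical serialization.
config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config[order(names(config))], file = tf)
  unname(tools::md5sum(tf))
}
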