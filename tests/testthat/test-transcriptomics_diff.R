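# Minimal two-arm expression fixture at a single timepoint.
toy_expression <- function(counts_treat, counts_ctrl, lengths,
                           origin = NULL, timepoint_h = 6) {
  n <- nrow(counts_treat)
  ids <- sprintf("g%02d", seq_len(n))
  counts <- cbind(counts_treat, counts_ctrl)
  rownames(counts) <- ids
  samples <- data.frame(
    sample_id = c(paste0("t", seq_len(ncol(counts_treat))),
                  paste0("c", seq_len(ncol(counts_ctrl)))),
    treatment = rep(c("phage", "control"),
                    c(ncol(counts_treat), ncol(counts_ctrl))),
    replicate = c(seq_len(ncol(counts_treat)), seq_len(ncol(counts_ctrl))),
    timepoint_h = timepoint_h, compartment = "rna",
    stringsAsFactors = FALSE
  )
  colnames(counts) <- samples$sample_id
  gi <- data.frame(gene_id = ids, length_bp = lengths,
                   origin = origin %||% rep("host", n),
                   stringsAsFactors = FALSE)
  expression_matrix(counts, gi, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("RPKM follows its definition and a per-cell formula oracle", {
  # 1000 reads on a 1000 bp gene in a 1e6-read library -> RPKM 1000
  m <- toy_expression(matrix(c(1000, 999000), 2, 1),
                      matrix(c(0, 1e6), 2, 1), lengths = c(1000, 5000))
  r <- rpkm(m)
  expect_equal(r$rpkm["g01", "t1"], 1000)
  expect_equal(r$rpkm["g01", "c1"], 0)
  expect_equal(r$log2rpkm["g01", "c1"], 0)  # log2(0 + 1)

  set.seed(13)
  counts <- matrix(rpois(24, 50), 6, 4,
                   dimnames = list(sprintf("g%02d", 1:6), paste0("s", 1:4)))
  lens <- sample(200:2000, 6)
  samples <- data.frame(sample_id = paste0("s", 1:4), treatment = "control",
                        replicate = 1:4, timepoint_h = 2,
                        compartment = "rna", stringsAsFactors = FALSE)
  mm <- expression_matrix(counts,
                          data.frame(gene_id = rownames(counts),
                                     length_bp = lens, origin = "host"),
                          samples)
  got <- rpkm(mm)$rpkm
  for (i in 1:6) for (j in 1:4) {
    expect_equal(got[i, j], counts[i, j] * 1e9 / (sum(counts[, j]) * lens[i]))
  }
  zero <- counts; zero[, 1] <- 0
  mm0 <- expression_matrix(zero, mm$gene_info, samples)
  expect_error(rpkm(mm0), "zero library size")
})

test_that("time-matched DE equals a brute-force reference and nulls stay null", {
  set.seed(31)
  base <- matrix(rnbinom(10 * 8, mu = 300, size = 20), 10, 8)
  base[1, 1:4] <- rnbinom(4, mu = 300 * 8, size = 20)  # spiked gene
  m <- toy_expression(base[, 1:4], base[, 5:8],
                      lengths = sample(300:3000, 10))
  de <- de_per_timepoint(m, "phage", "control")
  expect_equal(de$gene_id, sort(m$gene_info$gene_id))

  lg <- rpkm(m)$log2rpkm
  for (i in seq_len(nrow(de))) {
    g <- de$gene_id[i]
    a <- lg[g, 1:4]; b <- lg[g, 5:8]
    expect_equal(de$log2_fc[i], mean(a) - mean(b), tolerance = 1e-12)
    expect_equal(de$p_value[i], oracle_welch_p(a, b), tolerance = 1e-12)
  }
  expect_equal(de$fdr, oracle_bh(de$p_value), tolerance = 1e-12)
  expect_true(de$significant[de$gene_id == "g01"])
  expect_equal(de$direction[de$gene_id == "g01"], "over")

  # identical arms: zero significant genes
  m2 <- toy_expression(base[, 1:4], base[, 1:4],
                       lengths = m$gene_info$length_bp)
  de2 <- de_per_timepoint(m2, "phage", "control")
  expect_false(any(de2$significant))
})

test_that("condition correlation matches the textbook formula", {
  set.seed(17)
  counts <- matrix(rnbinom(5 * 8, mu = 200, size = 30), 5, 8)
  m <- toy_expression(counts[, 1:4], counts[, 5:8],
                      lengths = rep(1000, 5),
                      origin = rep("phage", 5))
  self <- correlate_conditions(m, "phage", "phage")
  expect_equal(self$r, 1)

  ab <- correlate_conditions(m, "phage", "control")
  ba <- correlate_conditions(m, "control", "phage")
  expect_equal(ab$r, ba$r)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 5, 4, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(round(r_hand, 3), 0.775)
  expect_equal(stats::cor(x, y), r_hand)
})

test_that("standardized expression has zero mean unit sd per gene", {
  d <- experiment_design()
  cfg <- simulation_config(d, n_genes = 30, n_features = 5, seed = 2)
  m <- generate_counts(cfg)$matrix
  z <- standardize_expression(m, "phage")
  nonconst <- setdiff(rownames(z$z), z$constant_genes)
  expect_gt(length(nonconst), 0)
  expect_equal(unname(rowMeans(z$z[nonconst, , drop = FALSE])),
               rep(0, length(nonconst)), tolerance = 1e-12)
  expect_equal(unname(apply(z$z[nonconst, , drop = FALSE], 1, sd)),
               rep(1, length(nonconst)), tolerance = 1e-12)

  # linear ramp standardizes to a symmetric sequence
  ramp <- scale(1:6)[, 1]
  expect_equal(ramp, -rev(ramp))
})

test_that("temporal classes recover generated early/middle/late labels", {
  accs <- vapply(1:20, function(s) {
    cfg <- simulation_config(experiment_design(), n_genes = 60,
                             n_features = 5, seed = 100 + s)
    cm <- generate_counts(cfg)
    z <- standardize_expression(cm$matrix, "phage")$z
    tc <- assign_temporal_class(z, window_h = c(2, 8))
    truth <- cm$phage_classes$class[match(tc$gene_id,
                                          cm$phage_classes$gene_id)]
    mean(tc$class == truth)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("a gene peaking at the window start is early; no self-switches", {
  z <- matrix(c(2, 1, 0, -1, -1, -1,
                -1, 0, 2, 1, -1, -1,
                -1, -1, 0, 2, 1, -1), 3, 6, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c(2, 4, 6, 8, 10, 12)))
  tc <- assign_temporal_class(z, window_h = c(2, 8))
  expect_equal(tc$class, c("early", "middle", "late"))
  both <- assign_temporal_class(z, z, window_h = c(2, 8))
  expect_false(any(both$switch))
  expect_error(assign_temporal_class(z, window_h = c(20, 30)), "window")
})

test_that("category aFC summarizes significant genes only", {
  rec <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    treatment = "phage_protist", timepoint_h = 6,
    log2_fc = c(1, 2, 1, 5), p_value = 0.001, fdr = 0.01,
    significant = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("over", "over", "over", "over"),
    stringsAsFactors = FALSE
  )
  cmap <- data.frame(gene_id = paste0("g", 1:4),
                     category = c("carbon", "carbon", "stress", "empty"),
                     stringsAsFactors = FALSE)
  s <- category_summary(rec, cmap, 6)
  expect_equal(s$aFC[s$category == "carbon"], 3.0)
  expect_equal(s$n_genes[s$category == "carbon"], 2)
  expect_equal(s$aFC[s$category == "stress"], 2.0)
  expect_false("empty" %in% s$category)  # only a non-significant gene
})

test_that("DE-count fold increase reproduces the study ratio", {
  expect_equal(fold_increase_in_de(216, 48)$ratio, 4.5)
  expect_equal(fold_increase_in_de(48, 48)$ratio, 1.0)
  und <- fold_increase_in_de(10, 0)
  expect_false(und$defined)
  expect_true(is.na(und$ratio))
})

test_that("counts TSV reader reconstructs the expression matrix", {
  set.seed(4)
  m <- toy_expression(matrix(rpois(12, 40), 3, 4),
                      matrix(rpois(12, 40), 3, 4), lengths = c(500, 800, 1200))
  tf <- tempfile(fileext = ".tsv"); gf <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene_id = rownames(m$counts), m$counts,
                                check.names = FALSE),
                     tf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$gene_info, gf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_expression_matrix(tf, gf, m$samples)
  expect_equal(back$counts, m$counts)
  expect_equal(back$gene_info$length_bp, m$gene_info$length_bp)
  unlink(c(tf, gf))
})
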