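small_design <- function() experiment_design()

test_that("identical configs give byte-identical outputs", {
  cfg <- simulation_config(small_design(), n_genes = 30, n_features = 20,
                           seed = 99)
  expect_identical(generate_abundances(cfg), generate_abundances(cfg))
  expect_identical(generate_counts(cfg), generate_counts(cfg))
  expect_identical(generate_feature_table(cfg, "endo"),
                   generate_feature_table(cfg, "endo"))
  expect_identical(generate_frrf(cfg), generate_frrf(cfg))
  # different compartments draw from distinct streams
  expect_false(identical(generate_feature_table(cfg, "endo")$table$heights[1],
                         generate_feature_table(cfg, "exo")$table$heights[1]))
  expect_error(simulation_config(small_design()), "seed")
})

test_that("abundances follow the infection narrative", {
  cfg <- simulation_config(small_design(), n_genes = 10, n_features = 10,
                           burst_size = 0, abundance_cv = 0, seed = 1)
  ab <- generate_abundances(cfg)
  ph <- ab[ab$organism == "phage" & ab$treatment == "phage", ]
  expect_true(all(ph$concentration <= 3e7 + 1e-6))  # burst 0: no production

  # ensemble: infected host declines, control does not
  host_end <- host_start <- ctrl_end <- ctrl_start <- numeric(50)
  for (s in 1:50) {
    cfg_s <- simulation_config(small_design(), n_genes = 10,
                               n_features = 10, seed = s)
    a <- generate_abundances(cfg_s)
    h <- a[a$organism == "host", ]
    host_start[s] <- mean(h$concentration[h$treatment == "phage" &
                                            h$timepoint_h == 2])
    host_end[s] <- mean(h$concentration[h$treatment == "phage" &
                                          h$timepoint_h == 12])
    ctrl_start[s] <- mean(h$concentration[h$treatment == "control" &
                                            h$timepoint_h == 2])
    ctrl_end[s] <- mean(h$concentration[h$treatment == "control" &
                                          h$timepoint_h == 12])
  }
  expect_true(all(host_end < host_start))
  expect_gte(mean(ctrl_end), mean(ctrl_start))

  # study start concentrations reproduced at the first timepoint
  a1 <- generate_abundances(simulation_config(small_design(), n_genes = 10,
                                              n_features = 10, seed = 7))
  h1 <- a1[a1$organism == "host" & a1$timepoint_h == 2, ]
  starts <- c(control = 1.9e7, phage = 1.7e7, protist = 2.2e7,
              phage_protist = 1.7e7)
  for (tr in names(starts)) {
    got <- mean(h1$concentration[h1$treatment == tr])
    expect_lt(abs(got - starts[[tr]]) / starts[[tr]], 0.15)
  }
  expect_true(all(a1$concentration >= 0))

  bad <- simulation_config(small_design(), n_genes = 10, n_features = 10,
                           seed = 1)
  bad$design$start_concentrations$control[["host"]] <- -1
  expect_error(generate_abundances(bad), "> 0")
})

test_that("count generator spikes effects and silences phage genes", {
  d <- small_design()
  # null limit: tiny dispersion, no effects -> host gene treatment/control
  # ratios concentrate at 1
  cfg0 <- simulation_config(d, n_genes = 40, n_features = 5,
                            count_dispersion = 1e-4, seed = 12)
  cm0 <- generate_counts(cfg0)
  sm <- cm0$matrix$samples
  host <- cm0$matrix$gene_info$gene_id[cm0$matrix$gene_info$origin == "host"]
  tcols <- sm$sample_id[sm$treatment == "phage" & sm$timepoint_h == 6]
  ccols <- sm$sample_id[sm$treatment == "control" & sm$timepoint_h == 6]
  ratio <- rowMeans(cm0$matrix$counts[host, tcols]) /
    rowMeans(cm0$matrix$counts[host, ccols])
  expect_equal(unname(mean(ratio)), 1, tolerance = 0.1)

  # phage genes are all-zero in phage-free treatments
  phg <- setdiff(rownames(cm0$matrix$counts), host)
  free <- sm$sample_id[sm$treatment %in% c("control", "protist")]
  expect_true(all(cm0$matrix$counts[phg, free] == 0))

  # spiked gene recovers its log2 effect in ensemble mean
  eff <- data.frame(entity_id = "host_0001", treatment = "phage",
                    timepoint_h = 6, log_fc = 2)
  rec <- vapply(1:100, function(s) {
    cfg <- simulation_config(d, n_genes = 40, n_features = 5,
                             count_effects = eff, seed = s)
    cm <- generate_counts(cfg)
    smx <- cm$matrix$samples
    tc <- smx$sample_id[smx$treatment == "phage" & smx$timepoint_h == 6]
    cc <- smx$sample_id[smx$treatment == "control" & smx$timepoint_h == 6]
    log2(mean(cm$matrix$counts["host_0001", tc]) /
           mean(cm$matrix$counts["host_0001", cc]))
  }, numeric(1))
  expect_equal(mean(rec), 2, tolerance = 0.15)
  expect_true(abs(mean(rec) - 2) < 0.3)

  # ledger carries the spiked entity; unknown entities error
  cfg <- simulation_config(d, n_genes = 40, n_features = 5,
                           count_effects = eff, seed = 1)
  expect_true("host_0001" %in% generate_counts(cfg)$ledger$entity_id)
  bad_eff <- data.frame(entity_id = "nope", treatment = "phage",
                        timepoint_h = 6, log_fc = 2)
  cfg_bad <- simulation_config(d, n_genes = 40, n_features = 5,
                               count_effects = bad_eff, seed = 1)
  expect_error(generate_counts(cfg_bad), "unknown gene")
})

test_that("feature generator spikes log10 effects and censors cells", {
  d <- small_design()
  # noiseless null: treatment minus control log10 means exactly 0
  cfg0 <- simulation_config(d, n_features = 10, n_genes = 5, peak_sigma = 0,
                            censor_fraction = 0, seed = 3)
  ft0 <- generate_feature_table(cfg0, "endo")
  lg <- log10(ft0$table$heights)
  sm <- ft0$table$samples
  tcols <- sm$sample_id[sm$treatment == "phage" & sm$timepoint_h == 6]
  ccols <- sm$sample_id[sm$treatment == "control" & sm$timepoint_h == 6]
  expect_equal(unname(rowMeans(lg[, tcols]) - rowMeans(lg[, ccols])),
               rep(0, 10))

  # spiked effect recovered in ensemble mean within 0.05
  eff <- data.frame(entity_id = "endo_feat_0001", treatment = "phage",
                    timepoint_h = 6, log_fc = 0.3)
  rec <- vapply(1:100, function(s) {
    cfg <- simulation_config(d, n_features = 10, n_genes = 5,
                             censor_fraction = 0,
                             feature_effects_endo = eff, seed = s)
    ft <- generate_feature_table(cfg, "endo")
    l <- log10(ft$table$heights)
    s2 <- ft$table$samples
    tc <- s2$sample_id[s2$treatment == "phage" & s2$timepoint_h == 6]
    cc <- s2$sample_id[s2$treatment == "control" & s2$timepoint_h == 6]
    mean(l["endo_feat_0001", tc]) - mean(l["endo_feat_0001", cc])
  }, numeric(1))
  expect_equal(mean(rec), 0.3, tolerance = 0.05 / 0.3)

  # fully censored feature is excluded by the detection filter downstream
  cfgc <- simulation_config(d, n_features = 10, n_genes = 5, seed = 3)
  ftc <- generate_feature_table(cfgc, "endo",
                                censor_features = c(endo_feat_0002 = 1))
  expect_true(all(ftc$table$heights["endo_feat_0002", ] == 0))
  flt <- detection_filter(ftc$table)
  expect_false(any(flt$detected["endo_feat_0002", ]))

  # annotation flags span all three confidence levels
  ann <- generate_feature_table(
    simulation_config(d, n_features = 200, n_genes = 5, seed = 8),
    "endo")$table$annotation
  lev <- annotation_confidence(ann$rt_match, ann$mz_match, ann$msms_match)
  expect_setequal(unique(lev), c("level_1", "level_2", "unidentified"))
})

test_that("FRRf generator encodes the protocol and the true Fv/Fm", {
  d <- small_design()
  prof <- default_fvfm_profile(d, sd_fvfm = 0)
  cfg <- simulation_config(d, n_genes = 5, n_features = 5,
                           fvfm_profile = prof, frrf_noise_sd = 0, seed = 5)
  fr <- generate_frrf(cfg)
  tr <- fr$traces[[1]]
  fl <- tr$flashlets
  expect_equal(nrow(fl), 5 * 140)  # 5 sequences of 100 + 40 flashlets
  one <- fl[fl$sequence == 1, ]
  expect_equal(sum(one$phase == "saturation"), 100)
  expect_equal(sum(one$phase == "relaxation"), 40)
  expect_equal(diff(one$time_us[1:2]), 2)
  expect_equal(diff(one$time_us[101:102]), 50)

  # noiseless: extracted Fv/Fm equals the configured mean exactly
  corr <- blank_correct(tr)
  sat1 <- corr$flashlets[corr$flashlets$phase == "saturation" &
                           corr$flashlets$sequence == 1, ]
  Fo <- sat1$fluorescence[1]
  Fm <- max(sat1$fluorescence) / (1 - (1 - 0.05)^99) # asymptote correction
  meta <- fr$truth[fr$truth$sample_id == tr$sample_id, ]
  expect_equal((meta$Fm - meta$Fo) / meta$Fm, meta$true_fvfm)
  fit <- fit_induction(corr)
  expect_equal(fv_fm(fit), meta$true_fvfm, tolerance = 1e-6)

  # infected arm at 2 h is 35% below the control mean
  t2 <- fr$truth[fr$truth$timepoint_h == 2, ]
  expect_equal(mean(t2$true_fvfm[t2$treatment == "phage"]),
               0.30 * (1 - 0.35), tolerance = 1e-9)
  expect_equal(mean(t2$true_fvfm[t2$treatment == "control"]), 0.30)

  bad_prof <- prof
  bad_prof$mean_fvfm[1] <- 1.2
  expect_error(simulation_config(d, n_genes = 5, n_features = 5,
                                 fvfm_profile = bad_prof, seed = 1),
               "\\(0, 1\\)")
})

test_that("MPN plate generator matches its Poisson well model", {
  zero <- generate_mpn_plates(0, c(1, 0.1), 8, 1, seed = 1)[[1]]
  expect_true(all(zero$n_positive == 0))
  huge <- generate_mpn_plates(1e9, 1, 24, 1, seed = 1)[[1]]
  expect_equal(huge$n_positive, 24L)
  # titer 1/mL, d=1, v=1 mL: positive fraction -> 1 - exp(-1)
  big <- generate_mpn_plates(1, 1, 10000, 1, seed = 2)[[1]]
  expect_equal(big$n_positive / 10000, 1 - exp(-1), tolerance = 0.02)
  expect_error(generate_mpn_plates(1, -1, 8, 1, seed = 1), "> 0")
  expect_error(generate_mpn_plates(-1, 1, 8, 1, seed = 1), ">= 0")
})
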