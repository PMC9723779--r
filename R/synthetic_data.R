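# Synthetic-data generator emulating the tri-trophic study design: abundance
# time series, negative-binomial count matrices, lognormal metabolite
# feature tables, FRRf flashlet traces, and MPN plates — all with ground
# truth ledgers and full seed determinism.

#' Construct a simulation configuration
#'
#' Bundles the experiment design with every generator parameter. Defaults
#' emulate the study conditions: 4 treatments x 4 replicates x 6 timepoints,
#' host ~2e7 cells/mL, phage 3e7 pfu/mL at MOI 1.1, protist 43 cells/mL,
#' 6-8 h latent period, detection threshold 10,000 raw peak height, and an
#' Fv/Fm profile with the control near 0.30, a 35% infection reduction at
#' 2 h deepening to 64% by 12 h, and a ~15% relative recovery in the
#' phage+protist arm near 5 h.
#'
#' @param design An [experiment_design()].
#' @param n_genes Total genes (host + phage).
#' @param phage_gene_fraction Fraction of genes of phage origin.
#' @param n_features Metabolite features per compartment.
#' @param count_dispersion Negative-binomial dispersion (var = mu + disp *
#'   mu^2); > 0.
#' @param peak_sigma SD of log10 peak heights across replicates.
#' @param detection_threshold Raw peak height detection limit.
#' @param censor_fraction Fraction of feature x sample cells censored to 0
#'   (missed detection).
#' @param count_effects,feature_effects_endo,feature_effects_exo Ground-truth
#'   effect tables: data frames `entity_id`, `treatment`, `timepoint_h`,
#'   `log_fc` (log2 scale for counts, log10 for peak heights).
#' @param fvfm_profile Data frame `treatment`, `timepoint_h`, `mean_fvfm`,
#'   `sd_fvfm`; all means in (0, 1). Default from
#'   [default_fvfm_profile()].
#' @param frrf_noise_sd Additive Gaussian instrument noise on flashlet
#'   fluorescence.
#' @param burst_size Phage released per lysed cell (free parameter; the
#'   study depicts a simplified burst of 4).
#' @param decline_fraction Host abundance fraction lost by the final
#'   timepoint in phage-bearing treatments.
#' @param growth_rate_h Host exponential growth rate in uninfected
#'   treatments, per hour.
#' @param abundance_cv Lognormal replicate noise CV on abundances.
#' @param seed Integer seed; mandatory, no hidden global randomness.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(design = experiment_design(),
                              n_genes = 500,
                              phage_gene_fraction = 0.2,
                              n_features = 500,
                              count_dispersion = 0.05,
                              peak_sigma = 0.1,
                              detection_threshold = 10000,
                              censor_fraction = 0.02,
                              count_effects = NULL,
                              feature_effects_endo = NULL,
                              feature_effects_exo = NULL,
                              fvfm_profile = default_fvfm_profile(design),
                              frrf_noise_sd = 0.05,
                              burst_size = 4,
                              decline_fraction = 0.5,
                              growth_rate_h = 0.01,
                              abundance_cv = 0.05,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (detection_threshold <= 0) stop("detection_threshold must be > 0")
  if (count_dispersion <= 0) stop("count_dispersion must be > 0")
  if (any(fvfm_profile$mean_fvfm <= 0 | fvfm_profile$mean_fvfm >= 1))
    stop("all Fv/Fm means must lie in (0, 1)")
  structure(
    list(design = design, n_genes = as.integer(n_genes),
         phage_gene_fraction = phage_gene_fraction,
         n_features = as.integer(n_features),
         count_dispersion = count_dispersion, peak_sigma = peak_sigma,
         detection_threshold = detection_threshold,
         censor_fraction = censor_fraction,
         count_effects = count_effects,
         feature_effects_endo = feature_effects_endo,
         feature_effects_exo = feature_effects_exo,
         fvfm_profile = fvfm_profile, frrf_noise_sd = frrf_noise_sd,
         burst_size = burst_size, decline_fraction = decline_fraction,
         growth_rate_h = growth_rate_h, abundance_cv = abundance_cv,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default true Fv/Fm profile
#'
#' Control and protist-only arms hold ~0.30 (the healthy-culture range is
#' 0.27-0.33); phage-bearing arms drop 35% below control at 2 h, deepening
#' linearly to 64% below by 12 h; the phage+protist arm additionally runs
#' 15% above the phage-only arm at 4-6 h (the pre-lysis energy demand
#' signal).
#'
#' @param design An `experiment_design`.
#' @param control_mean Control Fv/Fm (default 0.30).
#' @param sd_fvfm Replicate SD (default 0.01).
#' @return Data frame `treatment`, `timepoint_h`, `mean_fvfm`, `sd_fvfm`.
#' @export
default_fvfm_profile <- function(design, control_mean = 0.30,
                                 sd_fvfm = 0.01) {
  tps <- design$timepoints_h
  reduction <- 0.35 + (0.64 - 0.35) * (tps - min(tps)) / (max(tps) - min(tps))
  infected <- control_mean * (1 - reduction)
  boost <- ifelse(tps >= 4 & tps <= 6, 1.15, 1)
  prof <- list(
    control = rep(control_mean, length(tps)),
    protist = rep(control_mean, length(tps)),
    phage = infected,
    phage_protist = infected * boost
  )
  out <- do.call(rbind, lapply(treatment_names(design), function(tr)
    data.frame(treatment = tr, timepoint_h = tps, mean_fvfm = prof[[tr]],
               sd_fvfm = sd_fvfm, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# Run fn with a deterministic, restored RNG state derived from (seed, tag).
with_seed <- function(seed, tag, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  offs <- c(abundance = 11L, counts = 23L, endo = 37L, exo = 41L,
            frrf = 53L, mpn = 67L)
  set.seed(seed * 101L %% 1000003L + offs[[tag]])
  fn()
}

#' Generate abundance time series
#'
#' Host abundance grows slowly in uninfected arms; in phage-bearing arms it
#' holds roughly constant through the latent period and then declines to
#' `decline_fraction` below its start by the final timepoint. Free phage
#' rises after the latent period by `burst_size` per lysed cell; protist
#' abundance stays at its start value. Replicate noise is multiplicative
#' lognormal.
#'
#' @param config A `simulation_config`.
#' @return Data frame `organism`, `treatment`, `replicate`, `timepoint_h`,
#'   `concentration`.
#' @export
generate_abundances <- function(config) {
  d <- config$design
  conc0 <- config$start_concentrations %||% d$start_concentrations
  if (any(unlist(conc0) <= 0)) stop("start concentrations must be > 0")
  latent_mid <- mean(d$latent_period_h)
  tmax <- max(d$timepoints_h)
  sdlog <- sqrt(log(1 + config$abundance_cv^2))
  with_seed(config$seed, "abundance", function() {
    out <- list()
    for (tr in treatment_names(d)) {
      trt <- treatment(tr)
      h0 <- conc0[[tr]][["host"]]
      for (tp in d$timepoints_h) {
        lysed_frac <- if (trt$has_phage && tp > latent_mid)
          config$decline_fraction * (tp - latent_mid) / (tmax - latent_mid)
        else 0
        host_mu <- if (trt$has_phage) h0 * (1 - lysed_frac)
                   else h0 * exp(config$growth_rate_h * tp)
        rows <- data.frame(
          organism = "host", treatment = tr,
          replicate = seq_len(d$n_replicates), timepoint_h = tp,
          concentration = host_mu *
            exp(stats::rnorm(d$n_replicates, -sdlog^2 / 2, sdlog)),
          stringsAsFactors = FALSE
        )
        if (trt$has_phage) {
          p0 <- conc0[[tr]][["phage"]]
          phage_mu <- p0 + config$burst_size * h0 * lysed_frac
          rows <- rbind(rows, data.frame(
            organism = "phage", treatment = tr,
            replicate = seq_len(d$n_replicates), timepoint_h = tp,
            concentration = phage_mu *
              exp(stats::rnorm(d$n_replicates, -sdlog^2 / 2, sdlog)),
            stringsAsFactors = FALSE
          ))
        }
        if (trt$has_protist) {
          pr0 <- conc0[[tr]][["protist"]]
          rows <- rbind(rows, data.frame(
            organism = "protist", treatment = tr,
            replicate = seq_len(d$n_replicates), timepoint_h = tp,
            concentration = pr0 *
              exp(stats::rnorm(d$n_replicates, -sdlog^2 / 2, sdlog)),
            stringsAsFactors = FALSE
          ))
        }
        out[[length(out) + 1]] <- rows
      }
    }
    res <- do.call(rbind, out)
    res$concentration <- pmax(res$concentration, 0)
    rownames(res) <- NULL
    res
  })
}

# Phage temporal-class expression multiplier: Gaussian bump at the class
# peak time within the first infection cycle. Peaks sit on sampled
# timepoints (2, 6, 8 h for early/middle/late under the default design) so
# the realized peak is unambiguous at the sampling resolution.
phage_profile <- function(class, tp) {
  peak <- c(early = 2, middle = 6, late = 8)[[class]]
  exp(-((tp - peak)^2) / (2 * 1.5^2))
}

#' Generate an RNA-seq count matrix with ground truth
#'
#' Counts are negative-binomial around treatment x timepoint means. Null
#' host genes share their mean with the control; spiked genes differ by
#' `2^log_fc` at the stated treatment/timepoints. Phage genes are zero in
#' phage-free arms and follow early/middle/late temporal bumps in
#' phage-bearing arms. Library-size factors vary at most 2-fold.
#'
#' @param config A `simulation_config`.
#' @return List: `matrix` (an `expression_matrix`), `ledger` (spiked-effect
#'   data frame `entity_id`, `treatment`, `timepoint_h`, `true_log_fc`),
#'   `phage_classes` (data frame `gene_id`, `class`).
#' @export
generate_counts <- function(config) {
  d <- config$design
  n_phage <- round(config$n_genes * config$phage_gene_fraction)
  n_host <- config$n_genes - n_phage
  host_ids <- sprintf("host_%04d", seq_len(n_host))
  phage_ids <- if (n_phage > 0) sprintf("phage_%03d", seq_len(n_phage))
               else character(0)
  eff <- config$count_effects
  if (!is.null(eff)) {
    unknown <- setdiff(eff$entity_id, c(host_ids, phage_ids))
    if (length(unknown))
      stop("effect references unknown gene(s): ",
           paste(unknown, collapse = ", "))
  }
  samples <- enumerate_samples(d, "rna")
  with_seed(config$seed, "counts", function() {
    base_mu <- stats::rlnorm(n_host + n_phage, meanlog = log(200), sdlog = 1)
    names(base_mu) <- c(host_ids, phage_ids)
    lengths <- round(stats::runif(n_host + n_phage, 300, 3000))
    classes <- if (n_phage > 0)
      sample(c("early", "middle", "late"), n_phage, replace = TRUE)
    else character(0)
    # library-size factors within a 2-fold band
    libf <- exp(pmin(pmax(stats::rnorm(nrow(samples), 0, 0.15), -0.34), 0.34))

    counts <- matrix(0L, n_host + n_phage, nrow(samples),
                     dimnames = list(c(host_ids, phage_ids),
                                     samples$sample_id))
    size <- 1 / config$count_dispersion
    for (j in seq_len(nrow(samples))) {
      tr <- treatment(samples$treatment[j])
      tp <- samples$timepoint_h[j]
      mu <- base_mu
      if (n_phage > 0) {
        mu[phage_ids] <- if (tr$has_phage)
          base_mu[phage_ids] *
            vapply(classes, phage_profile, numeric(1), tp = tp)
        else 0
      }
      if (!is.null(eff)) {
        hit <- eff[eff$treatment == samples$treatment[j] &
                     eff$timepoint_h == tp, , drop = FALSE]
        if (nrow(hit))
          mu[hit$entity_id] <- mu[hit$entity_id] * 2^hit$log_fc
      }
      mu <- mu * libf[j]
      pos <- mu > 0
      counts[pos, j] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
    }
    gi <- data.frame(
      gene_id = c(host_ids, phage_ids),
      length_bp = lengths,
      origin = c(rep("host", n_host), rep("phage", n_phage)),
      stringsAsFactors = FALSE
    )
    ledger <- if (is.null(eff))
      data.frame(entity_id = character(), treatment = character(),
                 timepoint_h = numeric(), true_log_fc = numeric(),
                 stringsAsFactors = FALSE)
    else data.frame(entity_id = eff$entity_id, treatment = eff$treatment,
                    timepoint_h = eff$timepoint_h, true_log_fc = eff$log_fc,
                    stringsAsFactors = FALSE)
    list(matrix = expression_matrix(counts, gi, samples), ledger = ledger,
         phage_classes = data.frame(gene_id = phage_ids, class = classes,
                                    stringsAsFactors = FALSE))
  })
}

#' Generate a metabolite feature table with ground truth
#'
#' Log10 peak heights are Gaussian around per-feature means with SD
#' `peak_sigma`; spiked features shift their log10 mean by `log_fc` in the
#' stated treatment/timepoints; a `censor_fraction` of cells is zeroed to
#' emulate missed detection. Annotation flags are drawn so confidence
#' levels 1, 2 and unidentified all occur.
#'
#' @param config A `simulation_config`.
#' @param compartment `"endo"` or `"exo"`.
#' @param censor_features Optional named vector of per-feature censoring
#'   fractions overriding `config$censor_fraction`.
#' @return List: `table` (a `feature_table`), `ledger` (`entity_id`,
#'   `treatment`, `timepoint_h`, `true_log_fc`).
#' @export
generate_feature_table <- function(config, compartment = c("endo", "exo"),
                                   censor_features = NULL) {
  compartment <- match.arg(compartment)
  d <- config$design
  ids <- sprintf("%s_feat_%04d", compartment, seq_len(config$n_features))
  eff <- config[[paste0("feature_effects_", compartment)]]
  if (!is.null(eff)) {
    unknown <- setdiff(eff$entity_id, ids)
    if (length(unknown))
      stop("effect references unknown feature(s): ",
           paste(unknown, collapse = ", "))
  }
  samples <- enumerate_samples(d, compartment)
  with_seed(config$seed, compartment, function() {
    base_l10 <- stats::runif(config$n_features, 4.3, 6)
    names(base_l10) <- ids
    h <- matrix(0, config$n_features, nrow(samples),
                dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- base_l10
      if (!is.null(eff)) {
        hit <- eff[eff$treatment == samples$treatment[j] &
                     eff$timepoint_h == samples$timepoint_h[j], ,
                   drop = FALSE]
        if (nrow(hit))
          mu[hit$entity_id] <- mu[hit$entity_id] + hit$log_fc
      }
      h[, j] <- 10^stats::rnorm(config$n_features, mu, config$peak_sigma)
    }
    cf <- rep(config$censor_fraction, config$n_features)
    names(cf) <- ids
    if (!is.null(censor_features)) cf[names(censor_features)] <- censor_features
    cens <- matrix(stats::runif(length(h)), nrow(h)) < cf
    h[cens] <- 0
    ann <- data.frame(
      feature_id = ids,
      name = ifelse(stats::runif(config$n_features) < 0.5, "Other",
                    sprintf("compound_%04d", seq_len(config$n_features))),
      class = sample(c("amino acid", "nucleotide", "vitamin", "lipid",
                       "organic acid", "other"),
                     config$n_features, replace = TRUE),
      rt_match = stats::runif(config$n_features) < 0.6,
      mz_match = stats::runif(config$n_features) < 0.6,
      msms_match = stats::runif(config$n_features) < 0.6,
      ion_mode = sample(c("positive", "negative"), config$n_features,
                        replace = TRUE),
      stringsAsFactors = FALSE
    )
    ledger <- if (is.null(eff))
      data.frame(entity_id = character(), treatment = character(),
                 timepoint_h = numeric(), true_log_fc = numeric(),
                 stringsAsFactors = FALSE)
    else data.frame(entity_id = eff$entity_id, treatment = eff$treatment,
                    timepoint_h = eff$timepoint_h, true_log_fc = eff$log_fc,
                    stringsAsFactors = FALSE)
    list(table = feature_table(h, samples, ann, compartment),
         ledger = ledger)
  })
}

#' Generate FRRf acquisitions with ground truth
#'
#' One acquisition per treatment x replicate x timepoint: 5 sequences of
#' 100 saturation flashlets (2 us pitch) rising from Fo toward Fm under the
#' single-turnover closure model, then 40 relaxation flashlets (50 us pitch)
#' decaying toward Fo; additive Gaussian instrument noise; a paired
#' cell-free blank trace. The true (Fm - Fo)/Fm equals the configured
#' treatment x timepoint mean plus replicate-level variation.
#'
#' @param config A `simulation_config`.
#' @param fm_level Instrument-scale maximum yield (arbitrary units).
#' @param blank_level Cell-free background fluorescence.
#' @param sigma_closure Per-flashlet closure increment of the generator.
#' @return List: `traces` (named list of `frrf_trace`), `truth` (data frame
#'   `sample_id`, `treatment`, `replicate`, `timepoint_h`, `true_fvfm`,
#'   `Fo`, `Fm`).
#' @export
generate_frrf <- function(config, fm_level = 10, blank_level = 0.5,
                          sigma_closure = 0.05) {
  d <- config$design
  prof <- config$fvfm_profile
  if (any(prof$mean_fvfm <= 0 | prof$mean_fvfm >= 1))
    stop("fvfm_profile means must lie in (0, 1)")
  samples <- enumerate_samples(d, "physiology")
  n_seq <- 5; n_sat <- 100; n_rel <- 40
  sat_t <- (seq_len(n_sat) - 1) * 2
  rel_t <- max(sat_t) + seq_len(n_rel) * 50
  with_seed(config$seed, "frrf", function() {
    traces <- list()
    truth <- list()
    for (j in seq_len(nrow(samples))) {
      row <- samples[j, ]
      m <- prof$mean_fvfm[prof$treatment == row$treatment &
                            prof$timepoint_h == row$timepoint_h]
      if (length(m) != 1)
        stop(sprintf("fvfm_profile missing (%s, %g h)", row$treatment,
                     row$timepoint_h))
      s <- prof$sd_fvfm[prof$treatment == row$treatment &
                          prof$timepoint_h == row$timepoint_h]
      true_fvfm <- min(max(m + stats::rnorm(1, 0, s), 1e-3), 0.999)
      Fm <- fm_level
      Fo <- Fm * (1 - true_fvfm)
      fl <- do.call(rbind, lapply(seq_len(n_seq), function(sq) {
        sat <- Fo + (Fm - Fo) * closure_curve(n_sat, sigma_closure)
        rel <- Fo + (Fm - Fo) * exp(-(rel_t - max(sat_t)) / 200)
        data.frame(
          sequence = sq,
          flashlet_index = seq_len(n_sat + n_rel),
          phase = rep(c("saturation", "relaxation"), c(n_sat, n_rel)),
          time_us = c(sat_t, rel_t),
          fluorescence = pmax(
            c(sat, rel) + blank_level +
              stats::rnorm(n_sat + n_rel, 0, config$frrf_noise_sd), 0),
          stringsAsFactors = FALSE
        )
      }))
      blank <- fl
      blank$fluorescence <- pmax(
        blank_level + stats::rnorm(nrow(fl), 0, config$frrf_noise_sd), 0)
      traces[[row$sample_id]] <- frrf_trace(fl, blank = blank,
                                            sample_id = row$sample_id)
      truth[[length(truth) + 1]] <- data.frame(
        sample_id = row$sample_id, treatment = row$treatment,
        replicate = row$replicate, timepoint_h = row$timepoint_h,
        true_fvfm = true_fvfm, Fo = Fo, Fm = Fm, stringsAsFactors = FALSE
      )
    }
    list(traces = traces, truth = do.call(rbind, truth))
  })
}

#' Generate MPN plate outcomes
#'
#' Each well scores positive with probability
#' `1 - exp(-true_titer * dilution * volume)`, independently.
#'
#' @param true_titer True concentration, pfu/mL (>= 0).
#' @param dilution_factors Numeric vector of dilution factors (> 0).
#' @param wells_per_dilution Wells per level.
#' @param volume_mL Inoculum volume per well.
#' @param seed Integer seed.
#' @param n_series Number of independent dilution series.
#' @return List of `mpn_plate` objects, length `n_series`.
#' @export
generate_mpn_plates <- function(true_titer, dilution_factors,
                                wells_per_dilution, volume_mL, seed,
                                n_series = 1) {
  if (true_titer < 0) stop("true_titer must be >= 0")
  if (any(dilution_factors <= 0)) stop("dilution factors must be > 0")
  with_seed(seed, "mpn", function() {
    p_pos <- 1 - exp(-true_titer * dilution_factors * volume_mL)
    lapply(seq_len(n_series), function(i) {
      mpn_plate(dilution_factors, volume_mL, wells_per_dilution,
                stats::rbinom(length(dilution_factors), wells_per_dilution,
                              p_pos))
    })
  })
}

#' Default spiked-effect tables emulating the study's response structure
#'
#' Endometabolites and host genes respond mostly in the phage+protist arm
#' (the largest intracellular response), a smaller set in the phage-only
#' arm, and none in the protist-only arm; exometabolites respond in all
#' phage-bearing arms plus a couple of protist-only depletions.
#'
#' @param config_stub List with `n_genes`, `phage_gene_fraction`,
#'   `n_features` and `design` (used for ids and timepoints).
#' @param n_spiked Number of spiked entities per table.
#' @param log_fc Effect size on the analysis scale.
#' @return List with `count_effects`, `feature_effects_endo`,
#'   `feature_effects_exo`.
#' @export
default_effects <- function(config_stub, n_spiked = 20, log_fc = 2) {
  n_host <- config_stub$n_genes -
    round(config_stub$n_genes * config_stub$phage_gene_fraction)
  tps <- config_stub$design$timepoints_h
  mid <- tps[tps >= 4 & tps <= 8]
  gene_ids <- sprintf("host_%04d", seq_len(min(n_spiked, n_host)))
  ce <- expand.grid(entity_id = gene_ids, treatment = "phage_protist",
                    timepoint_h = mid, stringsAsFactors = FALSE)
  ce$log_fc <- log_fc
  endo_ids <- sprintf("endo_feat_%04d", seq_len(min(n_spiked,
                                                    config_stub$n_features)))
  fe <- expand.grid(entity_id = endo_ids, treatment = "phage_protist",
                    timepoint_h = mid, stringsAsFactors = FALSE)
  fe$log_fc <- 0.3
  exo_ids <- sprintf("exo_feat_%04d", seq_len(min(n_spiked,
                                                  config_stub$n_features)))
  fx <- expand.grid(entity_id = exo_ids, treatment = c("phage",
                                                       "phage_protist"),
                    timepoint_h = mid, stringsAsFactors = FALSE)
  fx$log_fc <- 0.3
  list(count_effects = ce, feature_effects_endo = fe,
       feature_effects_exo = fx)
}
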