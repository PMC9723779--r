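# Experiment-design and sample-metadata types shared by every stage.

TREATMENT_LEVELS <- c("control", "phage", "protist", "phage_protist")
COMPARTMENT_LEVELS <- c("endo", "exo", "rna", "physiology", "abundance")

#' Construct a treatment descriptor
#'
#' A treatment is one arm of the factorial co-culture design: the untreated
#' control, phage addition, protist addition, or both. The name and the two
#' flags determine each other bijectively.
#'
#' @param name One of `"control"`, `"phage"`, `"protist"`, `"phage_protist"`.
#' @return A list of class `treatment` with fields `name`, `has_phage`,
#'   `has_protist`.
#' @export
#' @examples
#' treatment("phage_protist")
treatment <- function(name) {
  name <- match.arg(name, TREATMENT_LEVELS)
  structure(
    list(
      name = name,
      has_phage = name %in% c("phage", "phage_protist"),
      has_protist = name %in% c("protist", "phage_protist")
    ),
    class = "treatment"
  )
}

#' Treatment name from phage/protist flags
#'
#' @param has_phage,has_protist Logical flags.
#' @return Treatment name string.
#' @export
treatment_name <- function(has_phage, has_protist) {
  if (has_phage && has_protist) "phage_protist"
  else if (has_phage) "phage"
  else if (has_protist) "protist"
  else "control"
}

#' Construct an experiment design
#'
#' The factorial frame every data table indexes into: treatments x replicates
#' x timepoints, plus starting concentrations and the phage latent period.
#' Defaults reproduce the study conditions: four treatments, four biological
#' replicates, sampling between 2 and 12 h every ~2 h, host ~2e7 cells/mL,
#' phage 3e7 pfu/mL, protist 43 cells/mL, 6-8 h latent period.
#'
#' @param treatments Character vector of treatment names.
#' @param n_replicates Replicates per treatment (>= 2; >= 3 recommended for
#'   the differential statistics — a warning is issued for 2).
#' @param timepoints_h Strictly increasing sampling times, hours post
#'   phage/protist addition (t = 0 is treatment start, never sampled).
#' @param start_concentrations Named list: per-treatment named numeric vector
#'   of organism -> concentration (cells or pfu per mL).
#' @param latent_period_h Length-2 numeric, (low, high) hours.
#' @param inoculation_host_concs Named numeric: host concentration (cells/mL)
#'   during the phage infection incubation, per phage-bearing treatment.
#'   These pre-wash densities set the MOI; `start_concentrations` are the
#'   post-wash densities at experiment start.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(treatments = TREATMENT_LEVELS,
                              n_replicates = 4,
                              timepoints_h = c(2, 4, 6, 8, 10, 12),
                              start_concentrations = default_start_concentrations(),
                              latent_period_h = c(6, 8),
                              inoculation_host_concs = c(phage = 2.8e7,
                                                         phage_protist = 2.9e7)) {
  treatments <- vapply(treatments, function(x) match.arg(x, TREATMENT_LEVELS),
                       character(1), USE.NAMES = FALSE)
  if (anyDuplicated(treatments))
    stop("duplicate treatment names in design")
  if (any(timepoints_h <= 0) || is.unsorted(timepoints_h, strictly = TRUE))
    stop("timepoints_h must be strictly increasing and > 0")
  if (n_replicates < 2)
    stop("n_replicates must be >= 2 (differential procedures need replicate means and variances)")
  if (n_replicates == 2)
    warning("n_replicates = 2 loads, but >= 3 is recommended for the statistics")
  if (length(latent_period_h) != 2 || latent_period_h[1] > latent_period_h[2])
    stop("latent_period_h must be (low, high) with low <= high")
  structure(
    list(
      treatments = lapply(treatments, treatment),
      n_replicates = as.integer(n_replicates),
      timepoints_h = as.numeric(timepoints_h),
      start_concentrations = start_concentrations,
      latent_period_h = as.numeric(latent_period_h),
      inoculation_host_concs = inoculation_host_concs
    ),
    class = "experiment_design"
  )
}

#' Study starting concentrations
#'
#' Host starting concentrations per treatment (cells/mL), free phage at
#' inoculation (pfu/mL) and protist concentration (cells/mL) as measured at
#' the start of the co-culture experiment.
#'
#' @return Named list keyed by treatment name; each element a named numeric
#'   vector with entries `host`, and where applicable `phage` and `protist`.
#' @export
default_start_concentrations <- function() {
  list(
    control       = c(host = 1.9e7),
    phage         = c(host = 1.7e7, phage = 3e7),
    protist       = c(host = 2.2e7, protist = 43),
    phage_protist = c(host = 1.7e7, phage = 3e7, protist = 43)
  )
}

treatment_names <- function(design) {
  vapply(design$treatments, `[[`, character(1), "name")
}

#' Enumerate the complete sample grid of a design
#'
#' @param design An `experiment_design`.
#' @param compartment Compartment label for the samples.
#' @return Data frame with columns `sample_id`, `treatment`, `replicate`,
#'   `timepoint_h`, `compartment`, one row per design cell.
#' @export
enumerate_samples <- function(design, compartment = "rna") {
  compartment <- match.arg(compartment, COMPARTMENT_LEVELS)
  grid <- expand.grid(
    replicate = seq_len(design$n_replicates),
    timepoint_h = design$timepoints_h,
    treatment = treatment_names(design),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$treatment, grid$timepoint_h, grid$replicate), ,
               drop = FALSE]
  data.frame(
    sample_id = sprintf("%s_T%g_r%d_%s", grid$treatment, grid$timepoint_h,
                        grid$replicate, compartment),
    treatment = grid$treatment,
    replicate = as.integer(grid$replicate),
    timepoint_h = grid$timepoint_h,
    compartment = compartment,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Validate a sample sheet against an experiment design
#'
#' Checks that the supplied samples tile the full treatment x timepoint x
#' replicate grid of the design, and that no sample refers to a treatment or
#' timepoint outside it. Duplicate design keys are a hard error.
#'
#' @param design An `experiment_design`.
#' @param samples Data frame with columns `sample_id`, `treatment`,
#'   `replicate`, `timepoint_h`, `compartment`.
#' @return Data frame of violations (`type`, `treatment`, `timepoint_h`,
#'   `replicate`, `detail`), zero rows when the design is complete. Ordered
#'   by treatment, then timepoint, then replicate.
#' @export
validate_design <- function(design, samples) {
  req <- c("sample_id", "treatment", "replicate", "timepoint_h", "compartment")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  key <- paste(samples$treatment, samples$replicate, samples$timepoint_h,
               samples$compartment, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    ids <- samples$sample_id[key == dup]
    stop("duplicate (treatment, replicate, timepoint, compartment): samples ",
         paste(ids, collapse = ", "))
  }

  tn <- treatment_names(design)
  expected <- expand.grid(
    replicate = seq_len(design$n_replicates),
    timepoint_h = design$timepoints_h,
    treatment = tn,
    stringsAsFactors = FALSE
  )
  ekey <- paste(expected$treatment, expected$replicate, expected$timepoint_h)
  skey <- paste(samples$treatment, samples$replicate, samples$timepoint_h)

  missing_idx <- which(!(ekey %in% skey))
  orphan_idx <- which(!(skey %in% ekey))

  viol <- rbind(
    if (length(missing_idx)) data.frame(
      type = "missing_cell",
      treatment = expected$treatment[missing_idx],
      timepoint_h = expected$timepoint_h[missing_idx],
      replicate = expected$replicate[missing_idx],
      detail = "no sample for this design cell",
      stringsAsFactors = FALSE
    ),
    if (length(orphan_idx)) data.frame(
      type = "orphan_sample",
      treatment = samples$treatment[orphan_idx],
      timepoint_h = samples$timepoint_h[orphan_idx],
      replicate = samples$replicate[orphan_idx],
      detail = paste0("sample ", samples$sample_id[orphan_idx],
                      " outside design grid"),
      stringsAsFactors = FALSE
    )
  )
  if (is.null(viol))
    viol <- data.frame(type = character(), treatment = character(),
                       timepoint_h = numeric(), replicate = integer(),
                       detail = character(), stringsAsFactors = FALSE)
  viol <- viol[order(viol$treatment, viol$timepoint_h, viol$replicate), ,
               drop = FALSE]
  rownames(viol) <- NULL
  viol
}

#' Read an experiment design from a YAML config file
#'
#' Keys: `treatments`, `replicates`, `timepoints_h`, `concentrations`
#' (treatment -> organism -> value), `latent_period_h`.
#'
#' @param path YAML file path.
#' @return An `experiment_design`.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  conc <- if (is.null(cfg$concentrations)) default_start_concentrations()
          else lapply(cfg$concentrations, function(x) unlist(x))
  experiment_design(
    treatments = cfg$treatments %||% TREATMENT_LEVELS,
    n_replicates = cfg$replicates %||% 4,
    timepoints_h = cfg$timepoints_h %||% c(2, 4, 6, 8, 10, 12),
    start_concentrations = conc,
    latent_period_h = unlist(cfg$latent_period_h %||% c(6, 8))
  )
}

#' Read a sample sheet CSV
#'
#' Header: `sample_id,treatment,replicate,timepoint_h,compartment`.
#'
#' @param path CSV file path.
#' @return Data frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  samples <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "treatment", "replicate", "timepoint_h", "compartment")
  missing <- setdiff(req, names(samples))
  if (length(missing))
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  samples
}

`%||%` <- function(a, b) if (is.null(a)) b else a
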