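# Synthetic coculture experiments with a ground-truth ledger.
#
# The generator encodes the statistical structure the analysis assumes:
# replicate CUEs are normal around a per-(culture, carbon) mean; coculture
# means equal the abundance-weighted expected CUE shifted additively by a
# planted interaction mode; final ratios are lognormal; Ct values follow a
# log-linear standard curve with Gaussian cycle noise.

#' Build and validate a simulation configuration
#'
#' Assembles the full description of a synthetic experiment. All fields are
#' validated before any data are generated. [default_study_config()]
#' returns a configuration mirroring the study design.
#'
#' @param mono_means data frame with one row per carbon source:
#'   `carbon_id`, `mean_cue_ec`, `mean_cue_pp` (noiseless monoculture CUE
#'   means) and optionally `preference` and `usage_group` ground-truth
#'   labels.
#' @param ratio_spec data frame `culture, carbon_id, log10_mean, log10_sd`:
#'   the lognormal distribution of the true final ratio per (coculture,
#'   carbon source).
#' @param interaction_spec data frame `culture, carbon_id, mode, delta`:
#'   planted interaction mode (`"positive"`, `"negative"`, `"neutral"`) and
#'   additive effect size on the CUE scale. Pairs not listed default to
#'   neutral.
#' @param cultures culture labels; the first two must be the monocultures
#'   (EC, PP), the rest cocultures.
#' @param n_replicates replicates per culture (default 3).
#' @param timepoints measurement times in hours (default 0 to 24 every 4 h).
#' @param cue_noise_sd replicate CUE standard deviation (default 0.02).
#' @param qpcr_spec list with `slope` (< 0), `intercept`, `ct_sd`,
#'   `dilution_factor`, `max_concentration`, `n_dilutions`,
#'   `n_standard_reps`.
#' @param a1_range range of the per-plate negative-control baseline
#'   absorbance (drawn uniformly once per plate).
#' @param total_dna total template DNA mass per qPCR sample (ng/uL), split
#'   between the species by the true ratio.
#' @param seed integer seed; one global seed feeds independent sub-streams
#'   per output so adding outputs never perturbs existing ones.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(mono_means, ratio_spec,
                              interaction_spec = NULL,
                              cultures = culture_labels(),
                              n_replicates = 3L,
                              timepoints = seq(0, 24, by = 4),
                              cue_noise_sd = 0.02,
                              qpcr_spec = list(),
                              a1_range = c(0.15, 0.25),
                              total_dna = 5,
                              seed = 1L) {
  stopifnot(is.data.frame(mono_means),
            all(c("carbon_id", "mean_cue_ec", "mean_cue_pp") %in%
                names(mono_means)))
  if (anyDuplicated(mono_means$carbon_id)) {
    stop("duplicate carbon_id in `mono_means`", call. = FALSE)
  }
  if (length(cultures) < 3L) {
    stop("need the two monocultures plus at least one coculture",
         call. = FALSE)
  }
  if (n_replicates < 2L) stop("`n_replicates` must be >= 2", call. = FALSE)
  if (!is.numeric(cue_noise_sd) || cue_noise_sd <= 0) {
    stop("`cue_noise_sd` must be > 0", call. = FALSE)
  }
  if (!length(timepoints) || max(timepoints) <= 0) {
    stop("`timepoints` must contain a positive extraction time",
         call. = FALSE)
  }
  cocultures <- cultures[-(1:2)]
  stopifnot(is.data.frame(ratio_spec),
            all(c("culture", "carbon_id", "log10_mean", "log10_sd") %in%
                names(ratio_spec)))
  if (!all(ratio_spec$culture %in% cocultures)) {
    stop("`ratio_spec` cultures must be cocultures", call. = FALSE)
  }
  if (any(!is.finite(ratio_spec$log10_mean)) ||
      any(ratio_spec$log10_sd < 0)) {
    stop("ratio_spec log10_mean must be finite and log10_sd >= 0",
         call. = FALSE)
  }
  need <- expand.grid(culture = cocultures,
                      carbon_id = mono_means$carbon_id,
                      stringsAsFactors = FALSE)
  rk <- paste(ratio_spec$culture, ratio_spec$carbon_id)
  if (!all(paste(need$culture, need$carbon_id) %in% rk)) {
    stop("`ratio_spec` must cover every (coculture, carbon) pair",
         call. = FALSE)
  }
  if (is.null(interaction_spec)) {
    interaction_spec <- data.frame(culture = character(0),
                                   carbon_id = character(0),
                                   mode = character(0), delta = numeric(0),
                                   stringsAsFactors = FALSE)
  }
  stopifnot(all(c("culture", "carbon_id", "mode", "delta") %in%
                names(interaction_spec)))
  if (!all(interaction_spec$mode %in%
           c("positive", "negative", "neutral"))) {
    stop("interaction modes must be positive/negative/neutral",
         call. = FALSE)
  }
  if (any(interaction_spec$delta < 0)) {
    stop("interaction effect sizes `delta` must be >= 0", call. = FALSE)
  }
  # slope default: ideal efficiency-2 amplifier, -1/log10(2) Ct per decade
  qd <- list(slope = -1 / log10(2), intercept = 24, ct_sd = 0.1,
             dilution_factor = 4, max_concentration = 10,
             n_dilutions = 6L, n_standard_reps = 3L)
  qpcr_spec <- utils::modifyList(qd, qpcr_spec)
  if (qpcr_spec$slope >= 0) stop("qPCR slope must be < 0", call. = FALSE)
  if (qpcr_spec$max_concentration <= 0 || qpcr_spec$dilution_factor <= 1) {
    stop("invalid qPCR dilution series", call. = FALSE)
  }
  if (total_dna <= 0) stop("`total_dna` must be > 0", call. = FALSE)
  structure(list(mono_means = mono_means, ratio_spec = ratio_spec,
                 interaction_spec = interaction_spec, cultures = cultures,
                 cocultures = cocultures,
                 n_replicates = as.integer(n_replicates),
                 timepoints = sort(unique(timepoints)),
                 cue_noise_sd = cue_noise_sd, qpcr_spec = qpcr_spec,
                 a1_range = a1_range, total_dna = total_dna,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic coculture experiment configuration\n")
  cat("  ", nrow(x$mono_means), " carbon sources, cultures: ",
      paste(x$cultures, collapse = ", "), "\n", sep = "")
  cat("  ", x$n_replicates, " replicates, timepoints ",
      paste(x$timepoints, collapse = "/"), " h, CUE noise sd ",
      x$cue_noise_sd, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Study-structured default configuration
#'
#' A configuration that mirrors the structure of the study design at 71
#' carbon sources: the preference partition 18 EC-preferred / 27
#' PP-preferred / 26 nonpreferential; usage groups of 41 (U1, low CUE in
#' every culture), 14 (U2, high CUE only in the 1:1 and 1000:1 cocultures)
#' and 16 (U3, high CUE in every culture except the *E. coli* monoculture),
#' with the cross-tabulation U2 = 10 EC / 2 none / 2 PP-preferred and U3
#' all PP-preferred; coculture final-ratio distributions centred so the
#' pooled median falls near 0.036 and ratios span roughly 1e-4 to 10, with
#' 12 carbon sources sharing identical ratio distributions across the three
#' cocultures; and interaction modes planted at the observed per-coculture
#' frequencies (1:1000 mostly negative, 1:1 mostly positive).
#'
#' @param seed integer seed for the configuration's random carbon-level
#'   ratio jitter and for the generated experiment.
#' @return a `sim_config`.
#' @export
default_study_config <- function(seed = 1L) {
  carbons <- sprintf("C%02d", 1:71)
  usage <- c(rep("U2", 14), rep("U3", 16), rep("U1", 41))
  preference <- rep("none", 71)
  preference[1:10] <- "EC"              # U2: 10 EC / 2 none / 2 PP
  preference[13:14] <- "PP"
  preference[15:30] <- "PP"             # U3: all PP-preferred
  preference[31:38] <- "EC"             # U1: 8 EC / 24 none / 9 PP
  preference[63:71] <- "PP"

  mean_ec <- ifelse(usage == "U3", 0.08,
             ifelse(preference == "EC", ifelse(usage == "U2", 0.20, 0.15),
             ifelse(preference == "PP", 0.05, 0.05)))
  mean_pp <- ifelse(usage == "U3", 0.70,
             ifelse(preference == "PP", ifelse(usage == "U2", 0.20, 0.15),
                    0.05))
  mean_ec[usage == "U2" & preference == "none"] <- 0.08
  mean_pp[usage == "U2" & preference == "none"] <- 0.08
  mono_means <- data.frame(carbon_id = carbons, mean_cue_ec = mean_ec,
                           mean_cue_pp = mean_pp, preference = preference,
                           usage_group = usage, stringsAsFactors = FALSE)

  # final-ratio structure: per-coculture centres, preference-linked carbon
  # offsets, small reproducible jitter; 12 carbons share one distribution
  # across the cocultures (no true between-coculture difference)
  set.seed(seed)
  jitter <- stats::rnorm(71, 0, 0.25)
  offset <- ifelse(preference == "EC", 1, ifelse(preference == "PP", -1, 0))
  centre <- c("1:1000" = -2.5, "1:1" = -1.44, "1000:1" = -0.8)
  ns_carbons <- carbons[c(31:37, 39:41, 63:64)]  # 7 EC / 3 none / 2 PP
  ratio_spec <- do.call(rbind, lapply(names(centre), function(cc) {
    mu <- centre[[cc]] + offset + jitter
    mu[carbons %in% ns_carbons] <- centre[["1:1"]] +
      offset[carbons %in% ns_carbons] + jitter[carbons %in% ns_carbons]
    data.frame(culture = cc, carbon_id = carbons, log10_mean = mu,
               log10_sd = 0.15, stringsAsFactors = FALSE)
  }))

  # planted interaction modes matching the observed per-coculture
  # frequencies while reproducing the usage-group CUE patterns: U2 carbons
  # are strongly synergistic in the 1:1 and 1000:1 cocultures
  plant <- function(cc, idx, mode, delta) {
    if (!length(idx)) return(NULL)
    data.frame(culture = cc, carbon_id = carbons[idx], mode = mode,
               delta = delta, stringsAsFactors = FALSE)
  }
  interaction_spec <- rbind(
    plant("1:1", 1:14, "positive", 0.6),
    plant("1000:1", 1:14, "positive", 0.6),
    plant("1:1000", 1:3, "negative", 0.1),
    plant("1:1000", 15:19, "negative", 0.1),
    plant("1:1000", 31:35, "positive", 0.1),
    plant("1:1000", 36:71, "negative", 0.1),
    plant("1:1", 31:49, "positive", 0.1),
    plant("1:1", 50:67, "negative", 0.1),
    plant("1000:1", 31:37, "positive", 0.1),
    plant("1000:1", 38:45, "negative", 0.1)
  )
  simulation_config(mono_means = mono_means, ratio_spec = ratio_spec,
                    interaction_spec = interaction_spec, seed = seed)
}

# derive the per-(culture, carbon) noiseless CUE means and the interaction
# ground truth from a config
.sim_truth <- function(config) {
  mm <- config$mono_means
  carbons <- mm$carbon_id
  ispec <- config$interaction_spec
  ikey <- paste(ispec$culture, ispec$carbon_id)
  rspec <- config$ratio_spec
  rkey <- paste(rspec$culture, rspec$carbon_id)

  rows <- list()
  for (cc in config$cocultures) {
    i <- match(paste(cc, carbons), rkey)
    log10_mean <- rspec$log10_mean[i]
    r <- 10^log10_mean
    p_a <- r / (1 + r)
    expected <- p_a * mm$mean_cue_ec + (1 - p_a) * mm$mean_cue_pp
    j <- match(paste(cc, carbons), ikey)
    mode <- ifelse(is.na(j), "neutral", ispec$mode[j])
    delta <- ifelse(is.na(j), 0, ispec$delta[j])
    measured <- expected + delta * (mode == "positive") -
      delta * (mode == "negative")
    rows[[cc]] <- data.frame(culture = cc, carbon_id = carbons,
                             mode = mode, delta = delta,
                             log10_ratio_mean = log10_mean,
                             ec_fraction = p_a,
                             expected_cue = expected,
                             measured_mean_cue = measured,
                             stringsAsFactors = FALSE)
  }
  interactions <- do.call(rbind, rows)
  rownames(interactions) <- NULL

  means <- rbind(
    data.frame(culture = config$cultures[1], carbon_id = carbons,
               mean_cue = mm$mean_cue_ec, stringsAsFactors = FALSE),
    data.frame(culture = config$cultures[2], carbon_id = carbons,
               mean_cue = mm$mean_cue_pp, stringsAsFactors = FALSE),
    cbind(interactions[, c("culture", "carbon_id")],
          mean_cue = interactions$measured_mean_cue)
  )
  list(interactions = interactions, means = means)
}

#' Generate a complete synthetic experiment
#'
#' Draws plate readings, a qPCR Ct table and a standards table from a
#' [simulation_config()], together with the ground-truth ledger. The same
#' seed yields byte-identical outputs; independent RNG sub-streams feed the
#' three outputs.
#'
#' Generative model:
#' \itemize{
#'   \item each plate (one culture x replicate) draws a baseline
#'     absorbance (the A1 negative-control level) uniformly from `a1_range`;
#'   \item each well's 24-h CUE is normal around the (culture, carbon)
#'     mean with sd `cue_noise_sd`; the raw 590 nm absorbance at time t is
#'     `baseline + (t / t_max) * CUE`, so A1-zeroing recovers the CUE
#'     exactly at t_max and ~0 signal at t = 0 (750 nm turbidity readings
#'     are emitted at 60\% of the 590 nm signal);
#'   \item coculture CUE means equal the abundance-weighted expected CUE
#'     shifted by the planted mode's `delta`;
#'   \item per-replicate final ratios are lognormal
#'     (`log10 ratio ~ N(log10_mean, log10_sd)`); a fixed total DNA mass is
#'     split between the species by the ratio and Ct values follow the
#'     standard curve plus `N(0, ct_sd)` cycle noise.
#' }
#'
#' @param config a `sim_config`.
#' @param dir optional output directory; when given, writes
#'   `plate_readings.csv`, `qpcr.csv`, `standards.csv`,
#'   `truth_carbons.csv` and `truth_interactions.csv`.
#' @return list with `readings`, `qpcr`, `standards`, `truth` (list of
#'   `carbons` and `interactions` data frames), `layout` and `config`,
#'   invisibly when `dir` is given.
#' @export
generate_experiment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  truth <- .sim_truth(config)
  carbons <- config$mono_means$carbon_id
  layout <- gen3_layout(n_carbons = length(carbons))
  carbon_wells <- layout$well[layout$role == "carbon"]

  # --- stream 1: plate readings ------------------------------------------
  set.seed(sub_seeds[1])
  t_max <- max(config$timepoints)
  plates <- expand.grid(replicate = seq_len(config$n_replicates),
                        culture = config$cultures,
                        stringsAsFactors = FALSE)[, c("culture", "replicate")]
  plates$plate_id <- sprintf("%s_r%d", gsub(":", "-", plates$culture),
                             plates$replicate)
  mean_key <- paste(truth$means$culture, truth$means$carbon_id)

  reading_blocks <- vector("list", nrow(plates))
  for (p in seq_len(nrow(plates))) {
    base590 <- stats::runif(1, config$a1_range[1], config$a1_range[2])
    base750 <- stats::runif(1, config$a1_range[1], config$a1_range[2])
    mu <- truth$means$mean_cue[match(paste(plates$culture[p], carbons),
                                     mean_key)]
    cue_rep <- stats::rnorm(length(carbons), mu, config$cue_noise_sd)
    blocks <- lapply(config$timepoints, function(t) {
      frac <- t / t_max
      data.frame(
        plate_id = plates$plate_id[p], culture = plates$culture[p],
        replicate = plates$replicate[p],
        well = c("A1", carbon_wells, "A1", carbon_wells),
        wavelength_nm = rep(c(590, 750), each = length(carbons) + 1L),
        time_h = t,
        absorbance = pmax(0, c(base590, base590 + frac * cue_rep,
                               base750, base750 + 0.6 * frac * cue_rep)),
        stringsAsFactors = FALSE)
    })
    reading_blocks[[p]] <- do.call(rbind, blocks)
  }
  readings <- do.call(rbind, reading_blocks)
  readings <- readings[order(readings$plate_id, readings$time_h,
                             readings$well), , drop = FALSE]
  rownames(readings) <- NULL

  # --- stream 2: qPCR table ----------------------------------------------
  set.seed(sub_seeds[2])
  qs <- config$qpcr_spec
  qgrid <- expand.grid(replicate = seq_len(config$n_replicates),
                       carbon_id = carbons, culture = config$cocultures,
                       stringsAsFactors = FALSE)
  ikey <- paste(truth$interactions$culture, truth$interactions$carbon_id)
  gi <- match(paste(qgrid$culture, qgrid$carbon_id), ikey)
  rk <- paste(config$ratio_spec$culture, config$ratio_spec$carbon_id)
  ri <- match(paste(qgrid$culture, qgrid$carbon_id), rk)
  log10r <- stats::rnorm(nrow(qgrid),
                         truth$interactions$log10_ratio_mean[gi],
                         config$ratio_spec$log10_sd[ri])
  r <- 10^log10r
  ec_q <- config$total_dna * r / (1 + r)
  pp_q <- config$total_dna / (1 + r)
  qpcr <- rbind(
    data.frame(culture = qgrid$culture, carbon_id = qgrid$carbon_id,
               replicate = qgrid$replicate, species = "EC",
               true_quantity = ec_q, stringsAsFactors = FALSE),
    data.frame(culture = qgrid$culture, carbon_id = qgrid$carbon_id,
               replicate = qgrid$replicate, species = "PP",
               true_quantity = pp_q, stringsAsFactors = FALSE)
  )
  qpcr$ct <- qs$intercept + qs$slope * log10(qpcr$true_quantity) +
    stats::rnorm(nrow(qpcr), 0, qs$ct_sd)
  qpcr <- qpcr[order(match(qpcr$culture, config$cultures), qpcr$carbon_id,
                     qpcr$replicate, qpcr$species), , drop = FALSE]
  rownames(qpcr) <- NULL

  # --- stream 3: standards -----------------------------------------------
  set.seed(sub_seeds[3])
  conc <- qs$max_concentration / qs$dilution_factor^(0:(qs$n_dilutions - 1L))
  sgrid <- expand.grid(rep = seq_len(qs$n_standard_reps),
                       concentration = conc, species = c("EC", "PP"),
                       stringsAsFactors = FALSE)
  standards <- data.frame(
    species = sgrid$species, concentration = sgrid$concentration,
    ct = qs$intercept + qs$slope * log10(sgrid$concentration) +
      stats::rnorm(nrow(sgrid), 0, qs$ct_sd),
    stringsAsFactors = FALSE)

  truth_carbons <- config$mono_means
  out <- list(readings = readings,
              qpcr = qpcr[, c("culture", "carbon_id", "replicate",
                              "species", "ct", "true_quantity")],
              standards = standards,
              truth = list(carbons = truth_carbons,
                           interactions = truth$interactions),
              layout = layout, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_readings(out$readings, file.path(dir, "plate_readings.csv"))
    utils::write.csv(out$qpcr, file.path(dir, "qpcr.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(out$standards, file.path(dir, "standards.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(out$truth$carbons, file.path(dir, "truth_carbons.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(out$truth$interactions,
                     file.path(dir, "truth_interactions.csv"),
                     row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
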