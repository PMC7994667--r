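# Seeded synthetic study generator. Emulates the design of the real study:
# four mESC lines sampled under serum/LIF (SL), 2i and Cdk8/19i; proteome
# timepoints 0,1,2,4,7,10,14 days in two 8-channel plexes per cell line
# (one per treatment, each with its own SL reference channels);
# phosphoproteome timepoints 0,0.5,1,2,6 h in one 11-channel plex per cell
# line; metabolome 3 treatments x 4 cell lines x 4 replicates. Ground truth
# (differential labels, trend modules, Gsk3 substrate pairs,
# post-transcriptional features, missingness classes, batch offsets) is
# exported so every downstream stage can be scored.
#
# RNG discipline: one stream per layer, seeded as master seed + a fixed
# offset (proteome +101, mRNA +202, phospho +303, metabolome +404), all on
# Mersenne-Twister with inversion normals; enabling or disabling one layer
# therefore never perturbs another.

LAYER_SEED_OFFSETS <- c(proteome = 101L, mrna = 202L, phospho = 303L,
                        metabolome = 404L)

layer_seed <- function(seed, layer) {
  (as.integer(seed) + LAYER_SEED_OFFSETS[[layer]]) %% .Machine$integer.max
}

set_layer_seed <- function(seed, layer) {
  set.seed(layer_seed(seed, layer), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulation configuration
#'
#' Default sizes mirror the real study's scale: ~4000 proteins, ~5000
#' phosphopeptidoforms, 440 metabolites, 4 cell lines; proteome timepoints
#' in days, phospho timepoints in hours. Effects are additive on the log2
#' scale; planted amplitudes are drawn in (4, 6) x `noise_sd` so every
#' planted effect is at least four noise standard deviations at its peak.
#'
#' @param seed master seed.
#' @param n_proteins,n_phosphosites,n_metabolites layer sizes.
#' @param n_cell_lines biological replicates (cell lines).
#' @param timepoints_protein days; first element must be the reference 0.
#' @param timepoints_phospho hours; first element must be the reference 0.
#' @param batch_sd per-feature-per-plex batch offset SD (log2).
#' @param noise_sd replicate noise SD (log2).
#' @param frac_shared_up,frac_shared_down fraction of features regulated in
#'   the same direction in both treatments.
#' @param frac_specific fraction regulated in only one treatment (split
#'   evenly between the two).
#' @param n_trend_modules number of trajectory shapes cycled over planted
#'   features (up to 4 distinct shapes: early-saturating rise, linear rise,
#'   transient pulse, late plateau).
#' @param n_gsk3_substrates planted Gsk3 priming-pair substrates.
#' @param n_posttx planted post-transcriptional features (protein effect
#'   with flat mRNA).
#' @param mar_rate,mec_rate metabolome missing-at-random cell rate and
#'   fraction of metabolites missing an entire condition.
#' @param frac_lowloc fraction of unplanted phosphosites with localization
#'   probability below the class-I cutoff.
#' @param met_replicates metabolome replicates per cell line and treatment.
#' @return `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 4000L,
                       n_phosphosites = 5000L,
                       n_metabolites = 440L,
                       n_cell_lines = 4L,
                       timepoints_protein = c(0, 1, 2, 4, 7, 10, 14),
                       timepoints_phospho = c(0, 0.5, 1, 2, 6),
                       batch_sd = 0.3,
                       noise_sd = 0.2,
                       frac_shared_up = 0.05,
                       frac_shared_down = 0.05,
                       frac_specific = 0.05,
                       n_trend_modules = 4L,
                       n_gsk3_substrates = 50L,
                       n_posttx = 40L,
                       mar_rate = 0.05,
                       mec_rate = 0.05,
                       frac_lowloc = 0.2,
                       met_replicates = 4L) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_shared_up, cfg$frac_shared_down, cfg$frac_specific)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop("planted fractions must lie in [0, 1] and sum to at most 1")
  }
  if (any(c(cfg$mar_rate, cfg$mec_rate, cfg$frac_lowloc) < 0) ||
      any(c(cfg$mar_rate, cfg$mec_rate, cfg$frac_lowloc) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  counts <- c(cfg$n_proteins, cfg$n_phosphosites, cfg$n_metabolites,
              cfg$n_cell_lines, cfg$n_trend_modules, cfg$met_replicates)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$timepoints_protein[1] != 0 || cfg$timepoints_phospho[1] != 0) {
    stop("the first timepoint must be the reference 0")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

# Trajectory shape library: curves over the treated timepoints, rescaled
# so the maximum over the sampled grid is exactly 1 (the planted amplitude
# is then the realized peak effect).
trend_shape <- function(module, t) {
  tmax <- max(t)
  s <- switch(((module - 1) %% 4) + 1,
              1 - exp(-3 * t / tmax),           # early-saturating rise
              t / tmax,                         # linear rise
              exp(-(log(t / (0.25 * tmax)))^2), # transient pulse, early peak
              ifelse(t >= 0.45 * tmax, 1, 0))   # late plateau
  s / max(s)
}

#' Simulate the proteome and matched mRNA layers with planted truth
#'
#' Baseline log2 abundances are Normal(25, 2); planted features add
#' module-shaped trajectory effects scaled to at least 4 x `noise_sd` at
#' peak; each plex carries per-feature additive batch offsets
#' Normal(0, `batch_sd`); replicate noise is Normal(0, `noise_sd`). The
#' mRNA layer carries the same effects as the proteins except for the
#' `n_posttx` planted post-transcriptional features, whose mRNA effect is
#' zero.
#'
#' @param config [sim_config()].
#' @return list with `proteome` (ExpressionMatrix of log2 abundances),
#'   `mrna` (ExpressionMatrix of log2 ratios with per-cell-line
#'   replicates), and `truth` (list: `features`, `effects`,
#'   `batch_offsets`, `posttx`).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  nf <- config$n_proteins
  tps <- config$timepoints_protein
  treated_tps <- tps[-1]
  lines <- paste0("CL", seq_len(config$n_cell_lines))
  features <- sprintf("P%05d", seq_len(nf))

  n_su <- round(config$frac_shared_up * nf)
  n_sd <- round(config$frac_shared_down * nf)
  n_sp <- round(config$frac_specific * nf)
  if (n_su + n_sd + n_sp > nf) stop("planted fractions exceed feature count")
  if (config$n_posttx > n_su + n_sd + n_sp) {
    stop("n_posttx exceeds the number of planted differential features")
  }

  set_layer_seed(config$seed, "proteome")
  label <- rep("null", nf)
  idx <- seq_len(n_su + n_sd + n_sp)
  label[idx] <- rep(c("shared_up", "shared_down", "specific"),
                    c(n_su, n_sd, n_sp))
  spec_idx <- which(label == "specific")
  spec_treat <- rep(c("2i", "Cdk8i"), length.out = length(spec_idx))
  direction <- ifelse(label == "shared_down", -1, 1)
  direction[spec_idx] <- sample(c(-1, 1), length(spec_idx), replace = TRUE)
  module <- ifelse(label == "null", NA_integer_,
                   rep_len(seq_len(config$n_trend_modules), nf))
  amplitude <- ifelse(label == "null", 0,
                      runif(nf, 4, 6) * config$noise_sd)

  # per-feature effect trajectory by treatment
  effect_at <- function(f, treatment) {
    if (label[f] == "null") return(numeric(length(treated_tps)))
    if (label[f] == "specific" &&
        spec_treat[match(f, spec_idx)] != treatment) {
      return(numeric(length(treated_tps)))
    }
    direction[f] * amplitude[f] * trend_shape(module[f], treated_tps)
  }
  eff <- list(
    "2i" = t(vapply(seq_len(nf), effect_at, numeric(length(treated_tps)),
                    treatment = "2i")),
    "Cdk8i" = t(vapply(seq_len(nf), effect_at, numeric(length(treated_tps)),
                       treatment = "Cdk8i")))

  baseline <- rnorm(nf, 25, 2)

  # design: one plex per cell line x treatment, 2 SL reference channels
  # (the second mirrors the doubled-input control) + treated timepoints
  design <- do.call(rbind, lapply(lines, function(cl) {
    do.call(rbind, lapply(c("2i", "Cdk8i"), function(tr) {
      px <- paste(cl, tr, sep = "_")
      rbind(
        data.frame(sample_id = paste0(px, "_d0_ref", 1:2), cell_line = cl,
                   treatment = "SL", timepoint = 0, plex = px,
                   replicate = 1:2, stringsAsFactors = FALSE),
        data.frame(sample_id = paste0(px, "_d", treated_tps), cell_line = cl,
                   treatment = tr, timepoint = treated_tps, plex = px,
                   replicate = 1, stringsAsFactors = FALSE))
    }))
  }))

  plexes <- unique(design$plex)
  batch_offsets <- matrix(rnorm(nf * length(plexes), 0, config$batch_sd),
                          nf, dimnames = list(features, plexes))

  # SL reference channels are doubled-input controls and so carry about
  # half the measurement noise of ordinary channels
  values <- matrix(NA_real_, nf, nrow(design),
                   dimnames = list(features, design$sample_id))
  for (s in seq_len(nrow(design))) {
    tr <- design$treatment[s]; tp <- design$timepoint[s]
    e <- if (tr == "SL") 0 else eff[[tr]][, match(tp, treated_tps)]
    ch_sd <- if (tr == "SL") config$noise_sd / 2 else config$noise_sd
    values[, s] <- baseline + e + batch_offsets[, design$plex[s]] +
      rnorm(nf, 0, ch_sd)
  }
  proteome <- expression_matrix(values, design, layer = "protein")

  planted <- which(label != "null")
  posttx <- sort(sample(planted, config$n_posttx))

  # mRNA: log2 ratios per cell line x treatment x timepoint
  set_layer_seed(config$seed, "mrna")
  mdesign <- do.call(rbind, lapply(lines, function(cl) {
    do.call(rbind, lapply(c("2i", "Cdk8i"), function(tr) {
      data.frame(sample_id = paste("mrna", cl, tr, paste0("d", treated_tps),
                                   sep = "_"),
                 cell_line = cl, treatment = tr, timepoint = treated_tps,
                 plex = "mrna", replicate = 1, stringsAsFactors = FALSE)
    }))
  }))
  # mRNA log2 ratios are averaged over sequencing libraries and carry less
  # dispersion than single-channel reporter ratios: half the proteome noise
  mvalues <- matrix(NA_real_, nf, nrow(mdesign),
                    dimnames = list(features, mdesign$sample_id))
  for (s in seq_len(nrow(mdesign))) {
    tr <- mdesign$treatment[s]; tp <- mdesign$timepoint[s]
    e <- eff[[tr]][, match(tp, treated_tps)]
    e[posttx] <- 0
    mvalues[, s] <- e + rnorm(nf, 0, config$noise_sd / 2)
  }
  mrna <- expression_matrix(mvalues, mdesign, layer = "mrna")
  attr(mrna, "ratio") <- TRUE

  truth_features <- data.frame(
    feature = features, label = label, direction = direction,
    module = module, amplitude = amplitude,
    specific_treatment = NA_character_, posttx = FALSE,
    stringsAsFactors = FALSE)
  truth_features$specific_treatment[spec_idx] <- spec_treat
  truth_features$posttx[posttx] <- TRUE

  effects_long <- do.call(rbind, lapply(c("2i", "Cdk8i"), function(tr) {
    data.frame(feature = rep(features, length(treated_tps)),
               treatment = tr,
               timepoint = rep(treated_tps, each = nf),
               effect = as.vector(eff[[tr]]), stringsAsFactors = FALSE)
  }))

  list(proteome = proteome, mrna = mrna,
       truth = list(features = truth_features, effects = effects_long,
                    batch_offsets = batch_offsets, posttx = features[posttx],
                    config = config))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_windows <- function(n, len = 15) {
  matrix(sample(AA20, n * len, replace = TRUE), n)
}

#' Simulate the phosphoproteome layer with planted Gsk3 substrate pairs
#'
#' Generates multiplicity-resolved phosphosite rows with random 15-mer
#' sequence windows. Each planted Gsk3 substrate emits two peptidoforms on
#' the same protein: a di-phosphorylated form (target S/T at the window
#' center, phospho-S/T priming residue four positions C-terminal) whose 2i
#' trajectory declines to at most -1 log2 by 2 h, and a priming-only
#' mono-phosphorylated form whose effect is non-negative. Decoys include
#' motif-matching pairs undergoing whole-site loss (both forms decline) and
#' motif-matching pairs with no change; the remaining sites are unrelated
#' singletons, a fraction of which carry ordinary regulation. A
#' configurable fraction of singleton localization probabilities falls
#' below the class-I cutoff 0.75.
#'
#' @param config [sim_config()].
#' @param truth optional truth list from [simulate_study()] to extend.
#' @return list with `phospho` (PhosphoSiteTable) and `truth` (the input
#'   truth extended with `$gsk3`).
#' @export
simulate_phospho_layer <- function(config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set_layer_seed(config$seed, "phospho")
  n_sub <- config$n_gsk3_substrates
  n_loss <- n_sub
  n_flat <- n_sub
  n_pairs <- n_sub + n_loss + n_flat
  n_single <- config$n_phosphosites - 2 * n_pairs
  if (n_single < 0) stop("n_phosphosites too small for the planted pairs")

  tps <- config$timepoints_phospho
  treated_tps <- tps[-1]
  lines <- paste0("CL", seq_len(config$n_cell_lines))

  design <- do.call(rbind, lapply(lines, function(cl) {
    px <- paste0("ph_", cl)
    rbind(
      data.frame(sample_id = paste0(px, "_h0_ref", 1:3), cell_line = cl,
                 treatment = "SL", timepoint = 0, plex = px, replicate = 1:3,
                 stringsAsFactors = FALSE),
      do.call(rbind, lapply(c("2i", "Cdk8i"), function(tr) {
        data.frame(sample_id = paste0(px, "_", tr, "_h", treated_tps),
                   cell_line = cl, treatment = tr, timepoint = treated_tps,
                   plex = px, replicate = 1, stringsAsFactors = FALSE)
      })))
  }))

  # paired rows: one 19-mer local sequence per pair; di window = 1..15
  # (site at window position 8), mono window = 5..19 (priming at +4)
  pair_class <- rep(c("substrate", "loss_decoy", "flat_decoy"),
                    c(n_sub, n_loss, n_flat))
  seqs <- matrix(sample(AA20, n_pairs * 19, replace = TRUE), ncol = 19)
  seqs[, 8] <- sample(c("S", "T"), n_pairs, replace = TRUE)
  seqs[, 12] <- sample(c("S", "T"), n_pairs, replace = TRUE)
  pair_protein <- sprintf("GP%04d", seq_len(n_pairs))
  pair_pos <- if (n_pairs > 0) sample(20:480, n_pairs, replace = TRUE)
              else integer(0)

  collapse <- function(m) apply(m, 1, paste, collapse = "")
  empty_sites <- data.frame(protein = character(), position = integer(),
                            amino_acid = character(),
                            localization_prob = numeric(),
                            multiplicity = integer(),
                            sequence_window = character(),
                            stringsAsFactors = FALSE)
  if (n_pairs > 0) {
    di_rows <- data.frame(
      protein = pair_protein, position = pair_pos,
      amino_acid = seqs[, 8], localization_prob = runif(n_pairs, 0.76, 1),
      multiplicity = 2L, sequence_window = collapse(seqs[, 1:15]),
      stringsAsFactors = FALSE)
    mono_rows <- data.frame(
      protein = pair_protein, position = pair_pos + 4L,
      amino_acid = seqs[, 12], localization_prob = runif(n_pairs, 0.76, 1),
      multiplicity = 1L, sequence_window = collapse(seqs[, 5:19]),
      stringsAsFactors = FALSE)
  } else {
    di_rows <- mono_rows <- empty_sites
  }

  # unrelated singleton sites
  swin <- random_windows(n_single)
  swin[, 8] <- sample(c("S", "T", "Y"), n_single, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15))
  low <- runif(n_single) < config$frac_lowloc
  single_rows <- data.frame(
    protein = sprintf("SP%05d", seq_len(max(n_single, 1)))[seq_len(n_single)],
    position = sample(10:800, n_single, replace = TRUE),
    amino_acid = swin[, 8],
    localization_prob = ifelse(low, runif(n_single, 0.3, 0.7499),
                               runif(n_single, 0.76, 1)),
    multiplicity = sample(1:3, n_single, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1)),
    sequence_window = collapse(swin),
    stringsAsFactors = FALSE)

  sites <- rbind(di_rows, mono_rows, single_rows)
  nr <- nrow(sites)

  # planted 2i effect trajectories per row
  decline <- function(t) -1.3 * (1 - exp(-t / 0.5))
  priming_up <- function(t) 0.4 * (1 - exp(-t / 1))
  eff2i <- matrix(0, nr, length(treated_tps))
  di_idx <- seq_len(n_pairs)
  mono_idx <- n_pairs + seq_len(n_pairs)
  plant <- function(rows, curve) {
    if (length(rows) > 0) {
      eff2i[rows, ] <<- matrix(curve, length(rows), length(treated_tps),
                               byrow = TRUE)
    }
  }
  plant(di_idx[pair_class != "flat_decoy"], decline(treated_tps))
  plant(mono_idx[pair_class == "substrate"], priming_up(treated_tps))
  plant(mono_idx[pair_class == "loss_decoy"], decline(treated_tps))

  # ordinary regulation on 10% of singletons, either treatment
  effcdk <- matrix(0, nr, length(treated_tps))
  if (n_single > 0) {
    moving <- 2 * n_pairs + which(runif(n_single) < 0.10)
    for (r in moving) {
      tr_sign <- sample(c(-1, 1), 1)
      amp <- runif(1, 4, 6) * config$noise_sd
      curve <- tr_sign * amp * (1 - exp(-treated_tps / 1))
      if (runif(1) < 0.5) eff2i[r, ] <- curve else effcdk[r, ] <- curve
    }
  }

  baseline <- rnorm(nr, 22, 2)
  plexes <- unique(design$plex)
  offsets <- matrix(rnorm(nr * length(plexes), 0, config$batch_sd), nr,
                    dimnames = list(NULL, plexes))
  values <- matrix(NA_real_, nr, nrow(design))
  for (s in seq_len(nrow(design))) {
    tr <- design$treatment[s]; tp <- design$timepoint[s]
    e <- if (tr == "SL") 0
         else if (tr == "2i") eff2i[, match(tp, treated_tps)]
         else effcdk[, match(tp, treated_tps)]
    ch_sd <- if (tr == "SL") config$noise_sd / 2 else config$noise_sd
    values[, s] <- baseline + e + offsets[, design$plex[s]] +
      rnorm(nr, 0, ch_sd)
  }

  phospho <- phospho_site_table(sites, values, design)
  gsk3 <- data.frame(
    protein = pair_protein, site_pos = pair_pos, priming_pos = pair_pos + 4L,
    di_id = phospho$site_id[di_idx], mono_id = phospho$site_id[mono_idx],
    class = pair_class, stringsAsFactors = FALSE)
  if (is.null(truth)) truth <- list(config = config)
  truth$gsk3 <- gsk3
  list(phospho = phospho, truth = truth)
}

#' Simulate the metabolome layer with planted missingness
#'
#' 3 treatments x `n_cell_lines` cell lines x `met_replicates` replicates.
#' Planted up/down sets shift treated samples by at least 4 x `noise_sd`;
#' missing-at-random cells are masked uniformly at `mar_rate`; `mec_rate`
#' of the metabolites lose one entire treatment block (missing in an entire
#' condition, the left-censored class).
#'
#' @param config [sim_config()].
#' @param truth optional truth list to extend.
#' @return list with `metabolome` (ExpressionMatrix, layer `"metabolite"`)
#'   and `truth` extended with `$metabolites`.
#' @export
simulate_metabolome <- function(config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set_layer_seed(config$seed, "metabolome")
  nf <- config$n_metabolites
  lines <- paste0("CL", seq_len(config$n_cell_lines))
  features <- sprintf("M%04d", seq_len(nf))

  design <- do.call(rbind, lapply(TREATMENTS, function(tr) {
    do.call(rbind, lapply(lines, function(cl) {
      data.frame(sample_id = paste("met", cl, tr,
                                   seq_len(config$met_replicates), sep = "_"),
                 cell_line = cl, treatment = tr, timepoint = 14,
                 plex = cl, replicate = seq_len(config$met_replicates),
                 stringsAsFactors = FALSE)
    }))
  }))
  design$timepoint[design$treatment == "SL"] <- 0

  n_su <- round(config$frac_shared_up * nf)
  n_sd <- round(config$frac_shared_down * nf)
  n_sp <- round(config$frac_specific * nf)
  label <- rep("null", nf)
  label[seq_len(n_su + n_sd + n_sp)] <-
    rep(c("shared_up", "shared_down", "specific"), c(n_su, n_sd, n_sp))
  spec_idx <- which(label == "specific")
  spec_treat <- rep(c("2i", "Cdk8i"), length.out = length(spec_idx))
  direction <- ifelse(label == "shared_down", -1, 1)
  direction[spec_idx] <- sample(c(-1, 1), length(spec_idx), replace = TRUE)
  amplitude <- ifelse(label == "null", 0, runif(nf, 4, 6) * config$noise_sd)

  baseline <- rnorm(nf, 20, 2)
  values <- matrix(NA_real_, nf, nrow(design),
                   dimnames = list(features, design$sample_id))
  for (s in seq_len(nrow(design))) {
    tr <- design$treatment[s]
    e <- numeric(nf)
    if (tr != "SL") {
      active <- label %in% c("shared_up", "shared_down") |
        (label == "specific" & spec_treat[match(seq_len(nf), spec_idx)] == tr)
      active[is.na(active)] <- FALSE
      e[active] <- direction[active] * amplitude[active]
    }
    values[, s] <- baseline + e + rnorm(nf, 0, config$noise_sd)
  }

  # missing-in-entire-condition: one treatment block fully missing
  n_mec <- round(config$mec_rate * nf)
  mec_feature <- sample(seq_len(nf), n_mec)
  mec_treatment <- sample(TREATMENTS, n_mec, replace = TRUE)
  for (i in seq_along(mec_feature)) {
    values[mec_feature[i], design$treatment == mec_treatment[i]] <- NA
  }
  # missing at random on the remaining observed cells
  if (config$mar_rate > 0) {
    for (attempt in 1:20) {
      cand <- values
      mask <- !is.na(cand) & matrix(runif(length(cand)) < config$mar_rate,
                                    nrow(cand))
      cand[mask] <- NA
      if (all(rowSums(!is.na(cand)) > 0)) { values <- cand; break }
      if (attempt == 20) stop("could not place MAR mask leaving every ",
                              "metabolite with at least one observation")
    }
  }

  met_truth <- data.frame(
    feature = features, label = label, direction = direction,
    amplitude = amplitude, specific_treatment = NA_character_,
    mec_treatment = NA_character_, stringsAsFactors = FALSE)
  met_truth$specific_treatment[spec_idx] <- spec_treat
  met_truth$mec_treatment[mec_feature] <- mec_treatment

  if (is.null(truth)) truth <- list(config = config)
  truth$metabolites <- met_truth
  list(metabolome = expression_matrix(values, design, layer = "metabolite"),
       truth = truth)
}

#' Generate well-separated synthetic trajectory modules
#'
#' Spherical Gaussian blobs in trajectory space for cluster-number
#' recovery experiments: module centers are drawn with standard deviation
#' `separation` x `within_sd` per coordinate, members scatter around their
#' center with `within_sd`.
#'
#' @param n_modules number of planted modules.
#' @param per_module rows per module.
#' @param n_dims trajectory length (dimensions).
#' @param within_sd within-module standard deviation.
#' @param separation center spread as a multiple of `within_sd`.
#' @param seed RNG seed.
#' @return list with `x` (rows x dims matrix) and `assignment`.
#' @export
make_trajectory_modules <- function(n_modules = 5, per_module = 50,
                                    n_dims = 12, within_sd = 0.2,
                                    separation = 10, seed = 1) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  centers <- matrix(rnorm(n_modules * n_dims, 0, separation * within_sd),
                    n_modules)
  assignment <- rep(seq_len(n_modules), each = per_module)
  x <- centers[assignment, , drop = FALSE] +
    matrix(rnorm(length(assignment) * n_dims, 0, within_sd),
           length(assignment))
  rownames(x) <- sprintf("T%04d", seq_along(assignment))
  list(x = x, assignment = assignment)
}
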