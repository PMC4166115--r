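#' Design of a synthetic two-color microarray experiment
#'
#' Describes the layout of a dual-stress time-course experiment: arrays are
#' treatment/control pairs (treated RNA in the Cy3/532 channel, control RNA in
#' the Cy5/635 channel on the same slide), one array per run x treatment x
#' time x biological replicate. Defaults reproduce the reference design:
#' 2 runs x 2 treatments (Psyr, Spod) x 3 times (1, 6, 24 h) x 5 replicates
#' = 60 arrays, each printed with 1287 experimental probe spots of which 26
#' probes are duplicated (1261 unique probes), plus control-class spots.
#'
#' @param n_runs number of experimental runs.
#' @param treatments character vector of treatment labels.
#' @param times_h numeric vector of sampling times (hours post-treatment).
#' @param n_reps biological replicates per design cell.
#' @param n_probes experimental probe spots per array (including duplicates).
#' @param n_duplicated number of probes printed twice per array.
#' @param control_classes named integer vector: spots per array for each
#'   control class. Recognised classes: `spike`, `polyA`, `blank`, `buffer`,
#'   `negative`.
#' @param seed integer seed used by [generate_array_experiment()].
#' @return object of class `array_design`.
#' @export
array_design <- function(n_runs = 2L,
                         treatments = c("Psyr", "Spod"),
                         times_h = c(1, 6, 24),
                         n_reps = 5L,
                         n_probes = 1287L,
                         n_duplicated = 26L,
                         control_classes = c(spike = 10L, polyA = 2L,
                                             blank = 4L, buffer = 4L,
                                             negative = 6L),
                         seed = 20140917L) {
  counts <- c(n_runs = n_runs, n_reps = n_reps, n_probes = n_probes)
  if (any(counts <= 0) || length(treatments) < 1 || length(times_h) < 1)
    stop("array_design: all design counts must be positive", call. = FALSE)
  if (n_duplicated < 0 || n_duplicated >= n_probes)
    stop("array_design: n_duplicated must be in [0, n_probes)", call. = FALSE)
  if (anyDuplicated(treatments) || anyDuplicated(times_h))
    stop("array_design: treatments and times_h must be unique", call. = FALSE)
  des <- list(n_runs = as.integer(n_runs), treatments = treatments,
              times_h = times_h, n_reps = as.integer(n_reps),
              n_probes = as.integer(n_probes),
              n_duplicated = as.integer(n_duplicated),
              control_classes = control_classes, seed = as.integer(seed))
  des$n_arrays <- des$n_runs * length(treatments) * length(times_h) * des$n_reps
  des$n_unique <- des$n_probes - des$n_duplicated
  class(des) <- "array_design"
  des
}

#' Effect and noise magnitudes for the microarray generator
#'
#' Houses the true values planted by [generate_array_experiment()]: the
#' fraction of probes with genuine treatment x time profiles, the standard
#' deviations of the probe, array, replicate-pair and residual effects (all on
#' the log2 scale), the additive Cy3 dye bias, the spot flagging rate, and the
#' background intensity distribution. The reference study reports no effect
#' magnitudes; defaults are package choices documented in the methods
#' vignette.
#'
#' @param frac_differential fraction of unique probes given non-zero true
#'   profiles.
#' @param effect_size peak |log2 fold change| of planted profiles.
#' @param effect_profiles optional matrix (one row per differential probe,
#'   one column per treatment x time cell in the order
#'   `paste(treatment, time, sep = "_")` with treatments and times in design
#'   order) of true log2 cell means. Overrides the built-in archetypes.
#' @param sd_probe SD of per-probe baseline abundance (log2 intensity).
#' @param sd_array SD of per-array additive effects (both channels).
#' @param sd_replicate SD of the per (run, replicate) random intercept added
#'   to the treated channel; this is the grouping the stage-2 model recovers.
#' @param sd_noise SD of the residual log2-ratio noise (split equally between
#'   the two channels).
#' @param dye_bias additive log2 offset of the treated (Cy3) channel,
#'   constant across arrays; removed by global normalization.
#' @param missing_rate probability that an experimental spot is flagged bad.
#' @param background_mean,background_sd background intensity distribution
#'   (linear intensity units; draws truncated at zero).
#' @param balance_signs if `TRUE` (default) archetype signs alternate so that
#'   planted effects sum to zero within each design cell; required for exact
#'   recovery through global normalization (see vignette).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(frac_differential = 0.1,
                        effect_size = 1.5,
                        effect_profiles = NULL,
                        sd_probe = 1,
                        sd_array = 0.3,
                        sd_replicate = 0.15,
                        sd_noise = 0.3,
                        dye_bias = 0.3,
                        missing_rate = 0.02,
                        background_mean = 100,
                        background_sd = 20,
                        balance_signs = TRUE) {
  sds <- c(sd_probe, sd_array, sd_replicate, sd_noise, background_sd)
  if (any(sds < 0)) stop("effect_spec: standard deviations must be >= 0",
                         call. = FALSE)
  if (frac_differential < 0 || frac_differential > 1)
    stop("effect_spec: frac_differential must be in [0, 1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("effect_spec: missing_rate must be in [0, 1)", call. = FALSE)
  out <- list(frac_differential = frac_differential, effect_size = effect_size,
              effect_profiles = effect_profiles, sd_probe = sd_probe,
              sd_array = sd_array, sd_replicate = sd_replicate,
              sd_noise = sd_noise, dye_bias = dye_bias,
              missing_rate = missing_rate, background_mean = background_mean,
              background_sd = background_sd, balance_signs = balance_signs)
  class(out) <- "effect_spec"
  out
}

# Cell labels in canonical order: treatment-major, time-minor.
design_cells <- function(design) {
  as.vector(t(outer(design$treatments, design$times_h, paste, sep = "_")))
}

# Built-in profile archetypes over the time course, scaled by effect_size.
# Each archetype is a treatments x times matrix of relative magnitudes; all
# differ between treatments so the planted truth is interaction-detectable.
profile_archetypes <- function(n_trt, n_time) {
  early <- c(1, 0.5, rep(0, n_time - 2))[seq_len(n_time)]
  late <- rev(early)
  mid <- rep(0, n_time); mid[ceiling(n_time / 2)] <- 1
  arch <- list(
    t1_early = rbind(early, matrix(0, n_trt - 1, n_time)),
    t2_late = rbind(matrix(0, n_trt - 1, n_time), late),
    opposed = rbind(mid, -mid, matrix(0, max(0, n_trt - 2), n_time))[seq_len(n_trt), , drop = FALSE],
    shared_shift = rbind(early, late, matrix(0, max(0, n_trt - 2), n_time))[seq_len(n_trt), , drop = FALSE]
  )
  lapply(arch, function(m) as.vector(t(m)))  # flatten treatment-major
}

# Build the truth table: one row per unique probe, 6 true cell means.
build_truth <- function(design, effects) {
  cells <- design_cells(design)
  n_u <- design$n_unique
  probe_id <- sprintf("P%04d", seq_len(n_u))
  truth <- matrix(0, n_u, length(cells), dimnames = list(probe_id, cells))
  n_de <- floor(effects$frac_differential * n_u)
  if (n_de > 0) {
    idx <- sort(sample.int(n_u, n_de))
    if (!is.null(effects$effect_profiles)) {
      prof <- as.matrix(effects$effect_profiles)
      if (ncol(prof) != length(cells))
        stop("effect_profiles must have one column per design cell",
             call. = FALSE)
      truth[idx, ] <- prof[rep_len(seq_len(nrow(prof)), n_de), ]
    } else {
      arch <- profile_archetypes(length(design$treatments),
                                 length(design$times_h))
      which_arch <- rep_len(seq_along(arch), n_de)
      sign <- if (isTRUE(effects$balance_signs)) {
        # alternate within archetype so each cell's planted mean is ~0
        stats::ave(rep(1, n_de), which_arch,
                   FUN = function(x) rep_len(c(1, -1), length(x)))
      } else sample(c(-1, 1), n_de, replace = TRUE)
      for (j in seq_len(n_de))
        truth[idx[j], ] <- sign[j] * effects$effect_size * arch[[which_arch[j]]]
    }
  }
  data.frame(probe_id = probe_id,
             is_differential = rowSums(truth != 0) > 0,
             truth, check.names = FALSE, row.names = NULL)
}

# Sample sheet for the full design; arrays A01..A60 in run/trt/time/rep order.
build_sample_sheet <- function(design) {
  g <- expand.grid(replicate = seq_len(design$n_reps),
                   time_h = design$times_h,
                   treatment = design$treatments,
                   run = seq_len(design$n_runs),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("run", "treatment", "time_h", "replicate")]
  g$array_id <- sprintf("A%02d", seq_len(nrow(g)))
  g[, c("array_id", "run", "treatment", "time_h", "replicate")]
}

#' Generate a synthetic two-color microarray experiment with known truth
#'
#' Simulates spot-level GenePix-style tables for every array of the design.
#' Channel intensities are generated on the log2 scale -- probe baseline +
#' array effect (+ dye bias + true cell mean + replicate-pair random intercept
#' on the treated channel) + residual noise -- then exponentiated, and an
#' additive background draw is added to each spot's foreground and recorded as
#' its background median. Duplicated probes share their true effect but get
#' independent noise. Control-class spots (spike, polyA, blank, buffer,
#' negative) are signal-free except spikes. Experimental spots are flagged bad
#' with probability `missing_rate`.
#'
#' @param design an [array_design()].
#' @param effects an [effect_spec()].
#' @param seed optional integer overriding `design$seed`.
#' @return list with components `spots` (long spot table over all arrays:
#'   `array_id`, `probe_id`, `spot_class`, `f_treat`, `b_treat`, `f_ctrl`,
#'   `b_ctrl`, `flag`), `samples` (the sample sheet) and `truth` (one row per
#'   unique probe with its true log2 cell-mean vector).
#' @export
generate_array_experiment <- function(design = array_design(),
                                      effects = effect_spec(),
                                      seed = NULL) {
  stopifnot(inherits(design, "array_design"), inherits(effects, "effect_spec"))
  set.seed(if (is.null(seed)) design$seed else as.integer(seed))

  samples <- build_sample_sheet(design)
  truth <- build_truth(design, effects)
  cells <- design_cells(design)
  n_u <- design$n_unique

  # spot layout of one array: unique probes once, first n_duplicated twice,
  # then control spots
  dup_ids <- truth$probe_id[seq_len(design$n_duplicated)]
  exp_ids <- c(truth$probe_id, dup_ids)
  ctrl <- design$control_classes
  ctrl_ids <- unlist(lapply(names(ctrl), function(cl)
    sprintf("%s_%02d", toupper(cl), seq_len(ctrl[[cl]]))), use.names = FALSE)
  ctrl_class <- rep(names(ctrl), times = unlist(ctrl))
  spot_ids <- c(exp_ids, ctrl_ids)
  spot_class <- c(rep("experimental", length(exp_ids)), ctrl_class)
  n_spots <- length(spot_ids)

  base <- stats::rnorm(n_u, mean = 10, sd = effects$sd_probe)
  names(base) <- truth$probe_id
  n_spike <- sum(spot_class == "spike")
  spike_base <- stats::rnorm(n_spike, mean = 11, sd = 0.5)
  truth_mat <- as.matrix(truth[, cells, drop = FALSE])
  rownames(truth_mat) <- truth$probe_id

  # replicate-pair random intercepts, shared across the arrays of a pair
  pair_key <- unique(samples[, c("run", "replicate")])
  pair_eff <- stats::rnorm(nrow(pair_key), 0, effects$sd_replicate)
  names(pair_eff) <- paste(pair_key$run, pair_key$replicate, sep = ":")

  array_eff <- stats::rnorm(nrow(samples), 0, effects$sd_array)
  ch_sd <- effects$sd_noise / sqrt(2)

  per_array <- vector("list", nrow(samples))
  for (a in seq_len(nrow(samples))) {
    s <- samples[a, ]
    cell <- paste(s$treatment, s$time_h, sep = "_")
    mu <- numeric(n_spots)                      # true log2 cell mean per spot
    is_exp <- spot_class == "experimental"
    mu[is_exp] <- truth_mat[spot_ids[is_exp], cell]
    log_base <- rep(NA_real_, n_spots)
    log_base[is_exp] <- base[spot_ids[is_exp]]
    log_base[spot_class == "spike"] <- spike_base
    blk <- pair_eff[paste(s$run, s$replicate, sep = ":")]

    lc <- log_base + array_eff[a] + stats::rnorm(n_spots, 0, ch_sd)
    lt <- log_base + array_eff[a] + effects$dye_bias +
      ifelse(is_exp, mu + blk, 0) + stats::rnorm(n_spots, 0, ch_sd)
    sig_c <- ifelse(is.na(lc), 0, 2^lc)         # signal-free controls
    sig_t <- ifelse(is.na(lt), 0, 2^lt)

    bg_t <- pmax(stats::rnorm(n_spots, effects$background_mean,
                              effects$background_sd), 0)
    bg_c <- pmax(stats::rnorm(n_spots, effects$background_mean,
                              effects$background_sd), 0)
    flag <- rep("good", n_spots)
    flag[is_exp & stats::runif(n_spots) < effects$missing_rate] <- "bad"

    per_array[[a]] <- data.frame(
      array_id = s$array_id, probe_id = spot_ids, spot_class = spot_class,
      f_treat = sig_t + bg_t, b_treat = bg_t,
      f_ctrl = sig_c + bg_c, b_ctrl = bg_c,
      flag = flag, stringsAsFactors = FALSE)
  }
  spots <- do.call(rbind, per_array)
  rownames(spots) <- NULL
  list(spots = spots, samples = samples, truth = truth)
}

#' Simulate normalized log2 ratios directly (ratio-level generator)
#'
#' Entry point one level below [generate_array_experiment()]: draws the
#' log2(Cy3/Cy5) ratios that spot-level generation plus filtering, background
#' subtraction and global normalization would deliver, skipping the intensity
#' layer. Used for large replicate simulations (e.g. null calibration of the
#' stage-2 tests) where regenerating spot tables dominates run time. The
#' planted model is identical: ratio = dye bias + true cell mean +
#' replicate-pair intercept + N(0, sd_noise); global normalization then
#' centers each array.
#'
#' @inheritParams generate_array_experiment
#' @param normalize center each array's ratios (default `TRUE`).
#' @return list with `log_ratios` (probe_id, array_id, log_ratio), `samples`,
#'   `truth`.
#' @export
simulate_log_ratios <- function(design = array_design(),
                                effects = effect_spec(),
                                seed = NULL, normalize = TRUE) {
  stopifnot(inherits(design, "array_design"), inherits(effects, "effect_spec"))
  set.seed(if (is.null(seed)) design$seed else as.integer(seed))
  samples <- build_sample_sheet(design)
  truth <- build_truth(design, effects)
  cells <- design_cells(design)
  truth_mat <- as.matrix(truth[, cells, drop = FALSE])
  n_u <- design$n_unique
  n_a <- nrow(samples)

  pair <- paste(samples$run, samples$replicate, sep = ":")
  pair_eff <- stats::rnorm(length(unique(pair)), 0, effects$sd_replicate)
  names(pair_eff) <- unique(pair)
  cell_of <- paste(samples$treatment, samples$time_h, sep = "_")

  m <- truth_mat[, cell_of, drop = FALSE] +
    matrix(effects$dye_bias + pair_eff[pair], n_u, n_a, byrow = TRUE) +
    matrix(stats::rnorm(n_u * n_a, 0, effects$sd_noise), n_u, n_a)
  if (normalize) m <- sweep(m, 2L, colMeans(m))
  lr <- data.frame(probe_id = rep(truth$probe_id, times = n_a),
                   array_id = rep(samples$array_id, each = n_u),
                   log_ratio = as.vector(m), stringsAsFactors = FALSE)
  list(log_ratios = lr, samples = samples, truth = truth)
}

#' Design of a synthetic LC-MS metabolite experiment
#'
#' Defaults reproduce the reference metabolite design: 2 experimental runs x
#' 2 treatments x treated/control x 8 biological replicates = 64 analyses,
#' each quantifying 33 metabolite fractions. A chosen fraction of fractions is
#' dichotomous (present only under some conditions, like camalexin appearing
#' only in the pathogen treatment); the rest are continuous with planted
#' log2-scale Trt, TC and Trt x TC effects.
#'
#' @param n_runs experimental runs.
#' @param treatments treatment labels.
#' @param n_reps biological replicates per run x treatment x TC cell.
#' @param n_fractions metabolite fractions quantified per analysis.
#' @param frac_dichotomous fraction of fractions present only under some
#'   conditions.
#' @param frac_affected fraction of continuous fractions given non-zero
#'   planted effects.
#' @param effect_trt,effect_tc,effect_inter planted log2 effect sizes.
#' @param sd_pool SD of the per (run, replicate) random intercept (log2).
#' @param sd_noise residual SD (log2).
#' @param mean_mass_mg,sd_mass_mg sample dry-mass distribution (the reference
#'   protocol weighs ~15 mg per sample).
#' @param seed integer seed.
#' @return object of class `metab_design`.
#' @export
metab_design <- function(n_runs = 2L, treatments = c("Psyr", "Spod"),
                         n_reps = 8L, n_fractions = 33L,
                         frac_dichotomous = 0.15, frac_affected = 0.3,
                         effect_trt = 1, effect_tc = 2, effect_inter = 1,
                         sd_pool = 0.25, sd_noise = 0.35,
                         mean_mass_mg = 15, sd_mass_mg = 1.5,
                         seed = 20140917L) {
  if (n_runs <= 0 || n_reps <= 0 || n_fractions <= 0 || length(treatments) < 1)
    stop("metab_design: all counts must be positive", call. = FALSE)
  if (frac_dichotomous < 0 || frac_dichotomous > 1)
    stop("metab_design: frac_dichotomous must be in [0, 1]", call. = FALSE)
  if (sd_pool < 0 || sd_noise < 0)
    stop("metab_design: standard deviations must be >= 0", call. = FALSE)
  out <- list(n_runs = as.integer(n_runs), treatments = treatments,
              tc_levels = c("T", "C"), n_reps = as.integer(n_reps),
              n_fractions = as.integer(n_fractions),
              frac_dichotomous = frac_dichotomous,
              frac_affected = frac_affected,
              effect_trt = effect_trt, effect_tc = effect_tc,
              effect_inter = effect_inter, sd_pool = sd_pool,
              sd_noise = sd_noise, mean_mass_mg = mean_mass_mg,
              sd_mass_mg = sd_mass_mg, seed = as.integer(seed))
  out$n_analyses <- out$n_runs * length(treatments) * 2L * out$n_reps
  class(out) <- "metab_design"
  out
}

#' Generate a synthetic LC-MS peak-area table with known truth
#'
#' Draws raw XIC peak areas for every analysis of the design. For continuous
#' fractions, log2 concentration = baseline + planted Exp/Trt/TC/TrtxTC
#' effects + replicate-pool intercept + noise; raw area = 2^log2 x sample mass
#' x area of the nearest-eluting internal standard (so the documented
#' normalization exactly inverts the nuisance factors). Dichotomous fractions
#' get zero area in the conditions where they are absent. Internal standards
#' are a series of alkyl 4-hydroxybenzoates at fixed retention times with
#' per-sample area variation.
#'
#' @param spec a [metab_design()].
#' @param seed optional integer overriding `spec$seed`.
#' @return list of class `peak_table`: `samples` (sample_id, run, treatment,
#'   tc, replicate, sample_mass_mg), `areas` (samples x fractions matrix of
#'   raw areas), `fraction_rt` (named retention times, min), `standards`
#'   (label + retention time), `standard_areas` (samples x standards matrix),
#'   and `truth` (per fraction: class, planted trt/tc/interaction effects,
#'   and the conditions where a dichotomous fraction is present).
#' @export
generate_metabolite_experiment <- function(spec = metab_design(), seed = NULL) {
  stopifnot(inherits(spec, "metab_design"))
  set.seed(if (is.null(seed)) spec$seed else as.integer(seed))

  g <- expand.grid(replicate = seq_len(spec$n_reps), tc = spec$tc_levels,
                   treatment = spec$treatments, run = seq_len(spec$n_runs),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("run", "treatment", "tc", "replicate")]
  g$sample_id <- sprintf("M%02d", seq_len(nrow(g)))
  g$sample_mass_mg <- pmax(stats::rnorm(nrow(g), spec$mean_mass_mg,
                                        spec$sd_mass_mg), 1)
  samples <- g[, c("sample_id", "run", "treatment", "tc", "replicate",
                   "sample_mass_mg")]
  n_s <- nrow(samples)

  frac_id <- sprintf("F%02d", seq_len(spec$n_fractions))
  frac_rt <- sort(stats::runif(spec$n_fractions, 2, 36))
  names(frac_rt) <- frac_id

  standards <- data.frame(label = paste0(c("methyl", "ethyl", "propyl",
                                           "butyl"), "_4HB"),
                          rt = c(8, 16, 24, 32))
  std_areas <- matrix(exp(stats::rnorm(n_s * nrow(standards),
                                       log(1e5), 0.15)),
                      n_s, nrow(standards),
                      dimnames = list(samples$sample_id, standards$label))

  n_dich <- round(spec$frac_dichotomous * spec$n_fractions)
  dich <- if (n_dich > 0) sort(sample.int(spec$n_fractions, n_dich)) else integer()
  cont <- setdiff(seq_len(spec$n_fractions), dich)
  n_aff <- floor(spec$frac_affected * length(cont))
  affected <- if (n_aff > 0) sort(sample(cont, n_aff)) else integer()

  truth <- data.frame(fraction = frac_id,
                      class = ifelse(seq_len(spec$n_fractions) %in% dich,
                                     "dichotomous", "continuous"),
                      beta_trt = 0, beta_tc = 0, beta_inter = 0,
                      present_in = "all", stringsAsFactors = FALSE)
  sgn <- rep_len(c(1, -1), n_aff)
  truth$beta_trt[affected] <- sgn * spec$effect_trt
  truth$beta_tc[affected] <- sgn * spec$effect_tc
  truth$beta_inter[affected] <- sgn * spec$effect_inter

  # condition restriction for dichotomous fractions: present in one
  # treatment's treated samples only (camalexin-like), alternating treatment
  if (n_dich > 0)
    truth$present_in[dich] <- paste0(rep_len(spec$treatments, n_dich), ":T")

  pool <- paste(samples$run, samples$replicate, sep = ":")
  pool_eff <- stats::rnorm(length(unique(pool)), 0, spec$sd_pool)
  names(pool_eff) <- unique(pool)

  x_trt <- as.numeric(samples$treatment == spec$treatments[2])
  x_tc <- as.numeric(samples$tc == "T")
  x_exp <- as.numeric(samples$run == 2)

  areas <- matrix(0, n_s, spec$n_fractions,
                  dimnames = list(samples$sample_id, frac_id))
  base_l2 <- stats::rnorm(spec$n_fractions, 4, 1)
  for (f in seq_len(spec$n_fractions)) {
    l2 <- base_l2[f] + 0.2 * x_exp + truth$beta_trt[f] * x_trt +
      truth$beta_tc[f] * x_tc + truth$beta_inter[f] * x_trt * x_tc +
      pool_eff[pool] + stats::rnorm(n_s, 0, spec$sd_noise)
    nearest <- which.min(abs(standards$rt - frac_rt[f]))
    conc <- 2^l2
    if (truth$class[f] == "dichotomous") {
      pi <- strsplit(truth$present_in[f], ":", fixed = TRUE)[[1]]
      present <- samples$treatment == pi[1] & samples$tc == pi[2]
      conc[!present] <- 0
    }
    areas[, f] <- conc * samples$sample_mass_mg * std_areas[, nearest]
  }
  structure(list(samples = samples, areas = areas, fraction_rt = frac_rt,
                 standards = standards, standard_areas = std_areas,
                 truth = truth),
            class = "peak_table")
}
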