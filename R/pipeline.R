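#' Run configuration for the end-to-end pipelines
#'
#' Collects every analysis option in one validated object. Either spot-table
#' inputs on disk (`input_dir` with GPR-like files plus `sample_sheet`) or a
#' synthetic specification (the default) must be given, never neither.
#'
#' @param input_dir directory of per-array spot tables, or `NULL` to
#'   simulate.
#' @param sample_sheet path to the sample-sheet CSV (required with
#'   `input_dir`).
#' @param design,effects synthetic generator specs used when `input_dir` is
#'   `NULL`.
#' @param bg_rule spot-filter threshold variant (see [filter_spots()]).
#' @param grouping stage-2 random-intercept grouping (see [fit_stage2()]).
#' @param fdr_alpha FDR level of the Trt x Time screen.
#' @param count_threshold raw-p threshold for the per-cell DE counts.
#' @param cluster_k probe-cluster cut level.
#' @param standardize probe-vector standardization (see [cluster_probes()]).
#' @param seed integer seed for synthetic generation.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, sample_sheet = NULL,
                       design = array_design(), effects = effect_spec(),
                       bg_rule = "sixty_pct_of_mean_plus_2sd",
                       grouping = "run_replicate",
                       fdr_alpha = 0.05, count_threshold = 0.001,
                       cluster_k = 6L, standardize = "zscore",
                       seed = NULL, out_dir = NULL) {
  if (!is.null(input_dir) && is.null(sample_sheet))
    stop("run_config: input_dir requires a sample_sheet", call. = FALSE)
  stopifnot(fdr_alpha > 0, fdr_alpha < 1,
            count_threshold > 0, count_threshold < 1, cluster_k >= 1)
  structure(list(input_dir = input_dir, sample_sheet = sample_sheet,
                 design = design, effects = effects, bg_rule = bg_rule,
                 grouping = grouping, fdr_alpha = fdr_alpha,
                 count_threshold = count_threshold,
                 cluster_k = as.integer(cluster_k),
                 standardize = standardize, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a flat key = value run-configuration file
#'
#' Lines of the form `key = value` (`#` comments and blank lines ignored).
#' Numeric-looking values are coerced; everything else stays character. Keys
#' match the arguments of [run_config()] plus the generator fields
#' `frac_differential`, `sd_noise`, `missing_rate`, `effect_size`.
#'
#' @param path configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad))
    stop("config: malformed line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  num <- suppressWarnings(as.numeric(vals))
  opts <- stats::setNames(as.list(ifelse(is.na(num), vals, num)), keys)
  for (k in keys) if (!is.na(num[match(k, keys)])) opts[[k]] <- num[match(k, keys)]
  eff_keys <- intersect(names(opts),
                        c("frac_differential", "sd_noise", "missing_rate",
                          "effect_size", "sd_replicate", "dye_bias"))
  effects <- do.call(effect_spec, opts[eff_keys])
  cfg_keys <- intersect(names(opts),
                        c("input_dir", "sample_sheet", "bg_rule", "grouping",
                          "fdr_alpha", "count_threshold", "cluster_k",
                          "standardize", "seed", "out_dir"))
  do.call(run_config, c(opts[cfg_keys], list(effects = effects)))
}

#' End-to-end microarray pipeline
#'
#' Executes the full chain: (1) load or simulate spot tables, (2) filter
#' spots, (3) compute and globally normalize log2 ratios, (4) collapse
#' duplicate probes, (5) stage-1 array-effect removal, (6) stage-2 per-probe
#' mixed models, (7) Tukey-Kramer adjustment, (8) BH FDR screen of the
#' Trt x Time F-tests, (9) DE counts/overlaps and Ward clustering of the
#' FDR-selected complete expression vectors. Every stage's row accounting is
#' recorded in the manifest; with synthetic input and known truth a recovery
#' report (sensitivity and observed false-discovery proportion against the
#' planted truth) is included.
#'
#' @param cfg a [run_config()].
#' @return list of class `pipeline_result`: `fits`, `fdr`, `counts`,
#'   `clustering`, `log_ratios`, `truth` (when synthetic), `recovery`,
#'   `manifest`.
#' @export
run_microarray_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  stages <- list()
  truth <- NULL
  if (is.null(cfg$input_dir)) {
    sim <- stage("simulate",
                 generate_array_experiment(cfg$design, cfg$effects,
                                           seed = cfg$seed))
    spots <- sim$spots; samples <- sim$samples; truth <- sim$truth
  } else {
    files <- list.files(cfg$input_dir, pattern = "\\.(gpr|txt)$",
                        full.names = TRUE)
    spots <- stage("read", do.call(rbind, lapply(files, read_spot_table)))
    samples <- stage("read", read_sample_sheet(cfg$sample_sheet))
  }
  stages$input <- nrow(spots)

  filt <- stage("filter", filter_spots(spots, bg_rule = cfg$bg_rule))
  stages$filter <- c(kept = nrow(filt$kept), rejected = nrow(filt$rejected))

  lrr <- stage("normalize", compute_log_ratios(filt$kept))
  stages$normalize <- c(kept = nrow(lrr$log_ratios),
                        rejected = nrow(lrr$rejected))

  lr <- stage("collapse", collapse_duplicates(lrr$log_ratios))
  stages$collapse <- nrow(lr)

  s1 <- stage("stage1", fit_stage1(lr, samples))
  stages$stage1 <- nrow(s1$residuals)

  fits <- stage("stage2", fit_stage2(s1, samples, grouping = cfg$grouping))
  stages$stage2 <- nrow(fits)

  fits <- stage("adjust", adjust_pvalues(fits))
  stages$adjust <- nrow(fits)

  fdr <- stage("fdr", fdr_select(stats::setNames(fits$p_int, fits$probe_id),
                                 alpha = cfg$fdr_alpha))
  stages$fdr <- fdr$n_selected

  counts <- stage("counts", count_de(fits, threshold = cfg$count_threshold))
  vecs <- expression_vectors(fits, probes = fdr$selected)
  clustering <- if (nrow(vecs) >= 2)
    stage("cluster", cluster_probes(vecs, k = min(cfg$cluster_k, nrow(vecs)),
                                    standardize = cfg$standardize))
  else NULL
  stages$cluster <- nrow(vecs)

  recovery <- NULL
  if (!is.null(truth)) {
    de_true <- truth$probe_id[truth$is_differential]
    sel <- fdr$selected
    recovery <- list(
      n_true = length(de_true), n_selected = length(sel),
      sensitivity = if (length(de_true))
        length(intersect(sel, de_true)) / length(de_true) else NA_real_,
      fdp = if (length(sel))
        length(setdiff(sel, de_true)) / length(sel) else 0)
  }

  manifest_opts <- list(bg_rule = cfg$bg_rule, grouping = cfg$grouping,
                        fdr_alpha = cfg$fdr_alpha,
                        count_threshold = cfg$count_threshold,
                        cluster_k = cfg$cluster_k,
                        standardize = cfg$standardize)
  result <- list(fits = fits, fdr = fdr, counts = counts,
                 clustering = clustering, log_ratios = lr, truth = truth,
                 recovery = recovery,
                 manifest = list(stages = stages, options = manifest_opts,
                                 seed = cfg$seed))
  if (!is.null(cfg$out_dir)) {
    tables <- list(
      log_ratios = lr,
      probe_fits = fits,
      fdr_selected = data.frame(probe_id = fdr$selected),
      de_counts = counts$cells,
      de_overlap = counts$overlap)
    if (!is.null(clustering))
      tables$cluster_assignments <- data.frame(
        probe_id = names(clustering$labels),
        cluster = as.integer(clustering$labels))
    write_results(tables, cfg$out_dir, options = manifest_opts,
                  seed = cfg$seed)
    if (!is.null(clustering))
      write_newick(clustering$tree,
                   file.path(cfg$out_dir, "probe_clusters.nwk"))
  }
  class(result) <- "pipeline_result"
  result
}

#' End-to-end metabolite pipeline
#'
#' Chains peak-area normalization, the continuous/dichotomous partition, and
#' the per-fraction mixed model; dichotomous fractions are reported as
#' presence tables only.
#'
#' @param spec a [metab_design()], or an existing `peak_table`.
#' @param seed optional seed for synthetic generation.
#' @param scale normalization variant (see [normalize_peak_areas()]).
#' @param min_presence continuous-class threshold.
#' @param out_dir optional output directory.
#' @return list: `peak_table`, `partition`, `fits`, `manifest`.
#' @export
run_metabolite_pipeline <- function(spec = metab_design(), seed = NULL,
                                    scale = "fraction_max",
                                    min_presence = 0.90, out_dir = NULL) {
  pt <- if (inherits(spec, "peak_table")) spec
  else generate_metabolite_experiment(spec, seed = seed)
  pt <- normalize_peak_areas(pt, scale = scale)
  part <- partition_metabolites(pt, min_presence = min_presence)
  fits <- fit_metabolite_model(pt, partition = part)
  manifest <- list(stages = list(
    analyses = nrow(pt$samples), fractions = ncol(pt$areas),
    continuous = sum(part$class == "continuous"),
    dichotomous = sum(part$class == "dichotomous"),
    fitted = sum(fits$method %in% c("lme", "ols"))),
    options = list(scale = scale, min_presence = min_presence), seed = seed)
  if (!is.null(out_dir))
    write_results(list(metabolite_partition = part, metabolite_fits = fits),
                  out_dir, options = manifest$options, seed = seed)
  list(peak_table = pt, partition = part, fits = fits, manifest = manifest)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write synthetic spot tables and sample sheet),
#' `microarray` (full expression pipeline), `metabolite` (metabolite
#' pipeline), `bioassay` (CFU computation from a CSV of growth observations).
#' Flags: `--config <file>`, `--seed <int>`, `--out <dir>`, and for
#' `bioassay` `--in <csv>`. Exits non-zero with a stage-named message on
#' error.
#'
#' @param args character vector (defaults to the trailing command line).
#' @return exit status, invisibly (0 on success).
#' @export
dualstress_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: dualstress <simulate|microarray|metabolite|bioassay>",
                 "[--config FILE] [--seed INT] [--out DIR] [--in CSV]")
  status <- tryCatch({
    if (length(args) < 1) stop(usage, call. = FALSE)
    cmd <- args[1]
    flag <- function(name, default = NULL) {
      i <- which(args == name)
      if (length(i) && i < length(args)) args[i + 1] else default
    }
    seed <- flag("--seed"); if (!is.null(seed)) seed <- as.integer(seed)
    out <- flag("--out", "dualstress_out")
    cfg_path <- flag("--config")
    cfg <- if (!is.null(cfg_path)) read_run_config(cfg_path) else run_config()
    cfg$seed <- if (!is.null(seed)) seed else cfg$seed
    switch(cmd,
           simulate = {
             sim <- generate_array_experiment(cfg$design, cfg$effects,
                                              seed = cfg$seed)
             write_spot_tables(sim$spots, file.path(out, "arrays"))
             utils::write.csv(sim$samples,
                              file.path(out, "sample_sheet.csv"),
                              row.names = FALSE)
             utils::write.csv(sim$truth, file.path(out, "truth.csv"),
                              row.names = FALSE)
           },
           microarray = {
             cfg$out_dir <- out
             run_microarray_pipeline(cfg)
           },
           metabolite = {
             run_metabolite_pipeline(seed = cfg$seed, out_dir = out)
           },
           bioassay = {
             infile <- flag("--in")
             if (is.null(infile)) stop("bioassay requires --in CSV",
                                       call. = FALSE)
             obs <- utils::read.csv(infile)
             obs$cfu_per_cm2 <- cfu_per_cm2(
               obs$colony_count, obs$dilution_factor, obs$plated_volume_ul,
               obs$extract_volume_ul,
               n_disks = if ("n_disks" %in% names(obs)) obs$n_disks else 1,
               disk_diameter_mm = if ("disk_diameter_mm" %in% names(obs))
                 obs$disk_diameter_mm else 6.25)
             dir.create(out, showWarnings = FALSE, recursive = TRUE)
             utils::write.csv(obs, file.path(out, "cfu.csv"),
                              row.names = FALSE)
           },
           stop(usage, call. = FALSE))
    0L
  }, error = function(e) {
    message("dualstress: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
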