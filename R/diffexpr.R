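#' Stage 1: remove array-level variability from log-ratios
#'
#' First stage of the two-stage mixed linear model. Array-to-array
#' hybridization and dye-binding variability is removed by fitting one effect
#' per array to the log2(Cy3/Cy5) ratios; with one fixed effect per array the
#' fitted array effect is the array's mean log-ratio, so the stage-1 residual
#' is the within-array centered value. When the input was already globally
#' normalized this stage is the identity (both remove the same per-array
#' mean).
#'
#' @param lr log-ratio table (`probe_id`, `array_id`, `log_ratio`).
#' @param samples sample sheet covering every array in `lr`.
#' @return list of class `stage1_fit`: `array_effects` (per-array estimate),
#'   `residuals` (`probe_id`, `array_id`, `residual`), `var_array` (variance
#'   of array effects, the stage-1 random component) and `var_resid`.
#' @export
fit_stage1 <- function(lr, samples) {
  missing_arrays <- setdiff(unique(lr$array_id), samples$array_id)
  if (length(missing_arrays))
    stop("fit_stage1: array(s) absent from sample sheet: ",
         paste(missing_arrays, collapse = ", "), call. = FALSE)
  eff <- tapply(lr$log_ratio, lr$array_id, mean)
  res <- data.frame(probe_id = lr$probe_id, array_id = lr$array_id,
                    residual = lr$log_ratio - eff[lr$array_id],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(
    array_effects = data.frame(array_id = names(eff),
                               effect = as.numeric(eff),
                               stringsAsFactors = FALSE),
    residuals = res,
    var_array = if (length(eff) > 1) stats::var(as.numeric(eff)) else 0,
    var_resid = stats::var(res$residual)), class = "stage1_fit")
}

# Canonical cell bookkeeping: cells in treatment-major, time-minor order.
cell_info_from <- function(samples) {
  trts <- unique(samples$treatment)
  times <- sort(unique(samples$time_h))
  data.frame(cell = as.vector(t(outer(trts, times, paste, sep = "_"))),
             treatment = rep(trts, each = length(times)),
             time_h = rep(times, times = length(trts)),
             stringsAsFactors = FALSE)
}

#' Stage 2: per-probe mixed model of residual log-ratios
#'
#' Second stage of the two-stage model: for each unique probe, the stage-1
#' residuals are modeled with fixed treatment, time (categorical) and
#' treatment x time effects plus a random intercept for the biological
#' replicate pair (`run:replicate` by default -- each array is a
#' treatment-control pair and the replicate pair is the repeated unit;
#' `grouping = "run"` groups at run level instead).
#'
#' Probes observed in every (replicate pair x design cell) combination form a
#' balanced complete-block design for which the REML solution has a closed
#' form (balanced ANOVA with the replicate pair as a random block); this path
#' is fully vectorized across probes. Incomplete probes are fitted with
#' [nlme::lme()]; if that fit fails or is singular, an ordinary-least-squares
#' fit is used and recorded (`method = "ols"`). When the estimated
#' random-intercept variance is zero the mixed estimates coincide with OLS.
#'
#' Per probe the fit reports: F-tests for Trt, Time and Trt x Time; the 6
#' expected differential-expression values Y(probe, Trt x Time) (cell means);
#' per-cell one-sample t-tests of each cell mean against zero; and the
#' variance components. Factors observed at a single level are marked
#' untestable (`NA`), not given degenerate p-values.
#'
#' @param e stage-1 residual table (`probe_id`, `array_id`, `residual`), or a
#'   `stage1_fit`.
#' @param samples sample sheet.
#' @param grouping random-intercept grouping factor.
#' @param engine `"auto"` (closed form when balanced, else `lme`), or force
#'   `"lme"` / `"ols"` for every probe.
#' @return data.frame of class `probe_fits`, one row per probe, with columns
#'   `probe_id`, `n_obs`, `complete`, `method`, `sigma2`, `sigma2_b`,
#'   `F_trt`, `p_trt`, `F_time`, `p_time`, `F_int`, `p_int`, and per design
#'   cell `mean_<cell>`, `n_<cell>`, `t_<cell>`, `p_<cell>`. The cell
#'   bookkeeping is attached as attribute `cell_info`.
#' @export
fit_stage2 <- function(e, samples, grouping = c("run_replicate", "run"),
                       engine = c("auto", "lme", "ols")) {
  grouping <- match.arg(grouping)
  engine <- match.arg(engine)
  if (inherits(e, "stage1_fit")) e <- e$residuals
  stopifnot(all(c("probe_id", "array_id", "residual") %in% names(e)))
  samples <- validate_sample_sheet(samples)
  missing_arrays <- setdiff(unique(e$array_id), samples$array_id)
  if (length(missing_arrays))
    stop("fit_stage2: array(s) absent from sample sheet: ",
         paste(missing_arrays, collapse = ", "), call. = FALSE)

  info <- cell_info_from(samples)
  idx <- match(e$array_id, samples$array_id)
  d <- data.frame(probe_id = e$probe_id, residual = e$residual,
                  trt = factor(samples$treatment[idx],
                               levels = unique(samples$treatment)),
                  time = factor(samples$time_h[idx],
                                levels = sort(unique(samples$time_h))),
                  block = if (grouping == "run_replicate")
                    paste(samples$run[idx], samples$replicate[idx], sep = ":")
                  else as.character(samples$run[idx]),
                  stringsAsFactors = FALSE)
  d$cell <- paste(d$trt, d$time, sep = "_")

  blocks <- sort(unique(d$block))
  cells <- info$cell
  # one column per (block, cell) slot; complete probes fill every slot once
  d$slot <- match(paste(d$block, d$cell),
                  as.vector(outer(blocks, cells, paste)))
  n_slots <- length(blocks) * length(cells)
  probes <- sort(unique(d$probe_id))
  pi_ <- match(d$probe_id, probes)
  # a slot filled twice means uncollapsed duplicates; route those probes to
  # the general path along with probes that have empty slots
  slot_fill <- tabulate((pi_ - 1L) * n_slots + d$slot,
                        nbins = length(probes) * n_slots)
  complete <- rowSums(matrix(slot_fill, length(probes), n_slots,
                             byrow = TRUE) == 1L) == n_slots

  out <- vector("list", length(probes))
  use_fast <- engine == "auto" & complete
  if (any(use_fast)) {
    fast_probes <- probes[use_fast]
    dd <- d[d$probe_id %in% fast_probes, ]
    E <- matrix(NA_real_, length(fast_probes), n_slots,
                dimnames = list(fast_probes, NULL))
    E[cbind(match(dd$probe_id, fast_probes), dd$slot)] <- dd$residual
    slot_cell <- rep(cells, each = length(blocks))
    slot_trt <- info$treatment[match(slot_cell, info$cell)]
    slot_time <- info$time_h[match(slot_cell, info$cell)]
    slot_block <- rep(blocks, times = length(cells))
    fast <- stage2_balanced(E, slot_trt, slot_time, slot_block, info)
    out[match(fast_probes, probes)] <- split(fast, seq_len(nrow(fast)))
  }
  slow_probes <- probes[!use_fast]
  if (length(slow_probes)) {
    ds <- split(d[d$probe_id %in% slow_probes,
                  c("probe_id", "residual", "trt", "time", "block", "cell")],
                d$probe_id[d$probe_id %in% slow_probes])
    for (p in slow_probes)
      out[[match(p, probes)]] <- stage2_general(ds[[p]], info, engine)
  }
  fits <- do.call(rbind, out)
  fits$probe_id <- probes
  fits$complete <- complete
  fits <- fits[, c("probe_id", "n_obs", "complete", "method",
                   "sigma2", "sigma2_b", "F_trt", "p_trt", "F_time",
                   "p_time", "F_int", "p_int",
                   setdiff(names(fits), c("probe_id", "n_obs", "complete",
                                          "method", "sigma2", "sigma2_b",
                                          "F_trt", "p_trt", "F_time",
                                          "p_time", "F_int", "p_int")))]
  rownames(fits) <- NULL
  attr(fits, "cell_info") <- info
  attr(fits, "grouping") <- grouping
  class(fits) <- c("probe_fits", "data.frame")
  fits
}

# Vectorized balanced complete-block ANOVA across probes.
# E: probes x slots residual matrix, one observation per slot.
stage2_balanced <- function(E, slot_trt, slot_time, slot_block, info) {
  n_b <- length(unique(slot_block))
  trts <- unique(info$treatment); times <- unique(info$time_h)
  n_trt <- length(trts); n_time <- length(times)
  n_c <- n_trt * n_time
  N <- n_b * n_c

  avg_by <- function(f) {
    lev <- unique(f)
    M <- vapply(lev, function(l) as.numeric(f == l) / sum(f == l),
                numeric(length(f)))
    m <- E %*% M; colnames(m) <- as.character(lev); m
  }
  grand <- rowMeans(E)
  cm <- avg_by(paste(slot_trt, slot_time, sep = "_"))
  cm <- cm[, info$cell, drop = FALSE]
  tm <- avg_by(slot_trt)[, as.character(trts), drop = FALSE]
  um <- avg_by(slot_time)[, as.character(times), drop = FALSE]
  bm <- avg_by(slot_block)

  ss_trt <- n_b * n_time * rowSums((tm - grand)^2)
  ss_time <- n_b * n_trt * rowSums((um - grand)^2)
  ss_cell <- n_b * rowSums((cm - grand)^2)
  ss_int <- pmax(ss_cell - ss_trt - ss_time, 0)
  ss_block <- n_c * rowSums((bm - grand)^2)
  ss_tot <- rowSums((E - grand)^2)
  ss_e <- pmax(ss_tot - ss_cell - ss_block, 0)
  df_e <- (n_c - 1) * (n_b - 1)
  ms_e <- ss_e / df_e
  ms_block <- ss_block / (n_b - 1)

  fp <- function(ss, df) {
    f <- (ss / df) / ms_e
    list(F = f, p = stats::pf(f, df, df_e, lower.tail = FALSE))
  }
  f_trt <- fp(ss_trt, n_trt - 1)
  f_time <- fp(ss_time, n_time - 1)
  f_int <- fp(ss_int, (n_trt - 1) * (n_time - 1))

  res <- data.frame(n_obs = N, method = "anova",
                    sigma2 = ms_e, sigma2_b = pmax((ms_block - ms_e) / n_c, 0),
                    F_trt = f_trt$F, p_trt = f_trt$p,
                    F_time = f_time$F, p_time = f_time$p,
                    F_int = f_int$F, p_int = f_int$p,
                    stringsAsFactors = FALSE)
  slot_cell <- paste(slot_trt, slot_time, sep = "_")
  for (cl in info$cell) {
    sub <- E[, slot_cell == cl, drop = FALSE]
    m <- rowMeans(sub)
    sdv <- sqrt(pmax(rowSums((sub - m)^2) / (n_b - 1), 0))
    tval <- m / (sdv / sqrt(n_b))
    res[[paste0("mean_", cl)]] <- m
    res[[paste0("n_", cl)]] <- n_b
    res[[paste0("t_", cl)]] <- tval
    res[[paste0("p_", cl)]] <- 2 * stats::pt(-abs(tval), df = n_b - 1)
  }
  res
}

# General (possibly unbalanced) per-probe fit: lme with OLS fallback.
stage2_general <- function(d, info, engine) {
  res <- data.frame(n_obs = nrow(d), method = NA_character_,
                    sigma2 = NA_real_, sigma2_b = NA_real_,
                    F_trt = NA_real_, p_trt = NA_real_,
                    F_time = NA_real_, p_time = NA_real_,
                    F_int = NA_real_, p_int = NA_real_,
                    stringsAsFactors = FALSE)
  for (cl in info$cell) {
    v <- d$residual[d$cell == cl]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    tval <- if (n >= 2 && stats::sd(v) > 0) m / (stats::sd(v) / sqrt(n))
    else NA_real_
    res[[paste0("mean_", cl)]] <- m
    res[[paste0("n_", cl)]] <- n
    res[[paste0("t_", cl)]] <- tval
    res[[paste0("p_", cl)]] <- if (!is.na(tval))
      2 * stats::pt(-abs(tval), df = n - 1) else NA_real_
  }
  d$trt <- droplevels(d$trt); d$time <- droplevels(d$time)
  can_trt <- nlevels(d$trt) >= 2
  can_time <- nlevels(d$time) >= 2
  if (!can_trt && !can_time) { res$method <- "untestable"; return(res) }

  terms <- c(if (can_trt) "trt", if (can_time) "time",
             if (can_trt && can_time) "trt:time")
  form <- stats::reformulate(terms, response = "residual")

  fit <- NULL
  if (engine != "ols" && length(unique(d$block)) > 1) {
    fit <- tryCatch(
      nlme::lme(form, random = ~ 1 | block, data = d,
                na.action = stats::na.omit,
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)[, "Variance"]))
    res$sigma2 <- fit$sigma^2
    res$sigma2_b <- vc[1]
    an <- tryCatch(stats::anova(fit, type = "marginal"),
                   error = function(e) NULL)
    if (!is.null(an)) {
      res$method <- "lme"
      pick <- function(term, col) if (term %in% rownames(an))
        an[term, col] else NA_real_
      res$F_trt <- pick("trt", "F-value"); res$p_trt <- pick("trt", "p-value")
      res$F_time <- pick("time", "F-value")
      res$p_time <- pick("time", "p-value")
      res$F_int <- pick("trt:time", "F-value")
      res$p_int <- pick("trt:time", "p-value")
      return(res)
    }
  }
  # OLS fallback with type-II model comparisons
  res$method <- "ols"
  full <- stats::lm(form, data = d)
  res$sigma2 <- summary(full)$sigma^2
  res$sigma2_b <- 0
  cmp <- function(reduced_terms, full_terms) {
    f0 <- if (length(reduced_terms))
      stats::lm(stats::reformulate(reduced_terms, "residual"), data = d)
    else stats::lm(residual ~ 1, data = d)
    f1 <- stats::lm(stats::reformulate(full_terms, "residual"), data = d)
    a <- tryCatch(stats::anova(f0, f1), error = function(e) NULL)
    if (is.null(a) || nrow(a) < 2 || is.na(a$F[2]))
      c(NA_real_, NA_real_) else c(a$F[2], a$`Pr(>F)`[2])
  }
  if (can_trt && can_time) {
    v <- cmp(c("trt", "time"), c("trt", "time", "trt:time"))
    res$F_int <- v[1]; res$p_int <- v[2]
    v <- cmp("time", c("trt", "time"))
    res$F_trt <- v[1]; res$p_trt <- v[2]
    v <- cmp("trt", c("trt", "time"))
    res$F_time <- v[1]; res$p_time <- v[2]
  } else if (can_trt) {
    v <- cmp(character(), "trt"); res$F_trt <- v[1]; res$p_trt <- v[2]
  } else {
    v <- cmp(character(), "time"); res$F_time <- v[1]; res$p_time <- v[2]
  }
  res
}

#' Tukey-Kramer adjustment of per-probe cell-mean tests
#'
#' Adjusts each probe's per-cell t-tests (cell mean against zero) for the
#' family of cells tested within that probe, using the studentized-range
#' distribution: for a cell with t statistic `t` and `k` populated cells, the
#' adjusted p-value is `ptukey(sqrt(2)*|t|, k, df)`. With a single populated
#' cell the adjusted value equals the raw one. Adjusted p-values are never
#' smaller than raw ones.
#'
#' @param fits a `probe_fits` table from [fit_stage2()].
#' @return the same table with `padj_<cell>` columns added.
#' @export
adjust_pvalues <- function(fits) {
  info <- attr(fits, "cell_info")
  stopifnot(!is.null(info))
  tcols <- paste0("t_", info$cell)
  ncols <- paste0("n_", info$cell)
  pcols <- paste0("p_", info$cell)
  tmat <- as.matrix(fits[, tcols])
  nmat <- as.matrix(fits[, ncols])
  pmat <- as.matrix(fits[, pcols])
  k <- rowSums(!is.na(tmat))
  for (j in seq_along(info$cell)) {
    padj <- ifelse(
      k >= 2 & !is.na(tmat[, j]),
      stats::ptukey(sqrt(2) * abs(tmat[, j]), nmeans = pmax(k, 2),
                    df = nmat[, j] - 1, lower.tail = FALSE),
      pmat[, j])
    fits[[paste0("padj_", info$cell[j])]] <- pmax(padj, pmat[, j], na.rm = FALSE)
  }
  fits
}

#' Tukey-Kramer pairwise comparisons of group means
#'
#' Classic Tukey-Kramer procedure for all pairwise comparisons among group
#' means with possibly unequal group sizes: the pooled within-group variance
#' feeds the studentized-range statistic
#' `q = |m_i - m_j| / sqrt(s2/2 * (1/n_i + 1/n_j))` with `k` groups and
#' pooled-error degrees of freedom.
#'
#' @param values numeric observations.
#' @param groups group labels (same length).
#' @return data.frame with one row per pair: `group_a`, `group_b`, `diff`,
#'   `q`, `p_raw` (unadjusted two-sided t) and `p_adj` (studentized range).
#' @export
tukey_contrasts <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  lev <- unique(groups)
  k <- length(lev)
  if (k < 2) stop("tukey_contrasts: need at least two groups", call. = FALSE)
  ns <- vapply(lev, function(l) sum(groups == l), numeric(1))
  ms <- vapply(lev, function(l) mean(values[groups == l]), numeric(1))
  df <- sum(ns - 1)
  if (df < 1) stop("tukey_contrasts: no residual degrees of freedom",
                   call. = FALSE)
  s2 <- sum(vapply(lev, function(l) {
    v <- values[groups == l]
    if (length(v) > 1) sum((v - mean(v))^2) else 0
  }, numeric(1))) / df
  pairs <- utils::combn(seq_len(k), 2)
  out <- data.frame(group_a = lev[pairs[1, ]], group_b = lev[pairs[2, ]],
                    stringsAsFactors = FALSE)
  dd <- ms[pairs[1, ]] - ms[pairs[2, ]]
  se2 <- s2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])
  out$diff <- as.numeric(dd)
  out$q <- as.numeric(abs(dd) / sqrt(se2 / 2))
  out$p_raw <- as.numeric(2 * stats::pt(-abs(dd) / sqrt(se2), df = df))
  out$p_adj <- as.numeric(stats::ptukey(out$q, nmeans = k, df = df,
                                        lower.tail = FALSE))
  out$p_adj <- pmax(out$p_adj, out$p_raw)
  out
}

#' Benjamini-Hochberg FDR screen
#'
#' Step-up procedure: sort the m finite p-values increasingly, find the
#' largest i with `p_(i) <= i/m * alpha`, and select everything up to it. Used
#' on the per-probe Trt x Time F-test p-values to screen probes at FDR
#' `alpha = 0.05`.
#'
#' @param pvals numeric p-values; names (or `ids`) identify the tests.
#' @param alpha FDR level.
#' @param ids identifiers parallel to `pvals`.
#' @return list: `selected` (ids), `threshold` (largest selected p, 0 when
#'   none), `n_selected`, `m` (number of finite p-values tested).
#' @export
fdr_select <- function(pvals, alpha = 0.05, ids = names(pvals)) {
  if (is.null(ids)) ids <- as.character(seq_along(pvals))
  keep <- is.finite(pvals)
  p <- pvals[keep]; id <- ids[keep]
  m <- length(p)
  if (m == 0)
    return(list(selected = character(), threshold = 0, n_selected = 0L, m = 0L))
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (!length(ok))
    return(list(selected = character(), threshold = 0, n_selected = 0L, m = m))
  kmax <- max(ok)
  list(selected = id[o][seq_len(kmax)], threshold = ps[kmax],
       n_selected = kmax, m = m)
}

#' Per-treatment/time differential-expression counts and overlaps
#'
#' Summarises, per treatment and sampling time, how many probes are
#' significant at a stated raw-p threshold on the per-cell t-test (default
#' p < 0.001, the threshold used for the headline counts), split into up- and
#' down-regulated by the sign of the cell mean, plus the cross-treatment
#' overlap per time point.
#'
#' @param fits a `probe_fits` table.
#' @param threshold raw p-value threshold.
#' @return list: `cells` (treatment, time_h, n_sig, n_up, n_down) and
#'   `overlap` (time_h, n_overlap over treatment pairs).
#' @export
count_de <- function(fits, threshold = 0.001) {
  info <- attr(fits, "cell_info")
  stopifnot(!is.null(info))
  sig <- lapply(seq_len(nrow(info)), function(j) {
    cl <- info$cell[j]
    p <- fits[[paste0("p_", cl)]]
    m <- fits[[paste0("mean_", cl)]]
    s <- !is.na(p) & p < threshold
    list(sig = fits$probe_id[s], up = fits$probe_id[s & m > 0],
         down = fits$probe_id[s & m < 0])
  })
  cells <- data.frame(treatment = info$treatment, time_h = info$time_h,
                      n_sig = vapply(sig, function(x) length(x$sig), 1L),
                      n_up = vapply(sig, function(x) length(x$up), 1L),
                      n_down = vapply(sig, function(x) length(x$down), 1L),
                      stringsAsFactors = FALSE)
  times <- unique(info$time_h)
  trts <- unique(info$treatment)
  overlap <- data.frame(time_h = times, n_overlap = NA_integer_)
  for (i in seq_along(times)) {
    sets <- lapply(trts, function(tr)
      sig[[which(info$treatment == tr & info$time_h == times[i])]]$sig)
    overlap$n_overlap[i] <- length(Reduce(intersect, sets))
  }
  list(cells = cells, overlap = overlap)
}

#' Extract the per-probe expression vectors for clustering
#'
#' Returns the matrix of expected differential-expression values
#' Y(probe, Trt x Time) -- one row per probe, one column per design cell --
#' for the given probes, keeping only probes with a complete vector (no
#' missing cell), mirroring the screened-then-complete subset that enters
#' clustering.
#'
#' @param fits a `probe_fits` table.
#' @param probes optional probe subset (e.g. the FDR-selected set).
#' @return numeric matrix with a `dropped_incomplete` attribute counting
#'   probes excluded for missing cells.
#' @export
expression_vectors <- function(fits, probes = NULL) {
  info <- attr(fits, "cell_info")
  stopifnot(!is.null(info))
  if (!is.null(probes)) fits <- fits[fits$probe_id %in% probes, , drop = FALSE]
  m <- as.matrix(fits[, paste0("mean_", info$cell), drop = FALSE])
  rownames(m) <- fits$probe_id
  colnames(m) <- info$cell
  ok <- stats::complete.cases(m)
  out <- m[ok, , drop = FALSE]
  attr(out, "dropped_incomplete") <- sum(!ok)
  out
}
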