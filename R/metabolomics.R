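#' Normalize LC-MS peak areas to sample mass and internal standards
#'
#' Each raw peak area is adjusted for sample size and for instrument drift:
#' `adjusted = (raw / sample_mass) / area(nearest internal standard)`, where
#' the internal standard (a series of alkyl 4-hydroxybenzoates spiked into
#' every extract) is matched to the fraction by closest retention time; an
#' exact tie is broken toward the earlier-eluting standard. The adjusted
#' values are then normalized to 100: by default each fraction is scaled so
#' its maximum across samples is 100 (`scale = "fraction_max"`); the
#' alternative reading scales each sample so its total is 100
#' (`scale = "sample_total"`).
#'
#' @param pt a `peak_table` (see [generate_metabolite_experiment()]).
#' @param scale normalization variant, see above.
#' @return the peak table with a `normalized` matrix added (samples x
#'   fractions, scaled to 100) and `adjusted` (pre-scaling values).
#' @export
normalize_peak_areas <- function(pt, scale = c("fraction_max",
                                               "sample_total")) {
  scale <- match.arg(scale)
  stopifnot(inherits(pt, "peak_table"))
  if (any(pt$standard_areas <= 0)) {
    bad <- rownames(pt$standard_areas)[apply(pt$standard_areas <= 0, 1, any)]
    stop("normalize_peak_areas: zero internal-standard area in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(pt$samples$sample_mass_mg <= 0))
    stop("normalize_peak_areas: non-positive sample mass", call. = FALSE)
  nearest <- vapply(pt$fraction_rt, function(rt) {
    dd <- abs(pt$standards$rt - rt)
    which(dd == min(dd))[1]  # tie -> earlier-eluting standard
  }, integer(1))
  adj <- pt$areas / pt$samples$sample_mass_mg / pt$standard_areas[, nearest]
  norm <- if (scale == "fraction_max") {
    mx <- apply(adj, 2, max)
    mx[mx == 0] <- 1
    sweep(adj, 2, mx, "/") * 100
  } else {
    tot <- rowSums(adj)
    tot[tot == 0] <- 1
    adj / tot * 100
  }
  pt$adjusted <- adj
  pt$normalized <- norm
  pt$scale <- scale
  pt
}

#' Partition metabolite fractions into continuous and dichotomous classes
#'
#' Fractions detected in at least `min_presence` of the samples have a
#' continuous distribution and are eligible for the mixed model; fractions
#' present only under some conditions (such as camalexin, which appears only
#' in pathogen-treated tissue) are dichotomous and analysed as
#' presence/absence only -- there are not enough observations to model them.
#'
#' @param pt a normalized `peak_table` (after [normalize_peak_areas()]).
#' @param min_presence minimum detection fraction for the continuous class.
#' @param floor detection floor: a value must exceed it to count as present.
#' @return data.frame per fraction: `fraction`, `class`, `presence_rate`, and
#'   presence counts per treatment x TC condition.
#' @export
partition_metabolites <- function(pt, min_presence = 0.90, floor = 0) {
  stopifnot(inherits(pt, "peak_table"), !is.null(pt$normalized))
  pres <- pt$normalized > floor
  rate <- colMeans(pres)
  cond <- paste(pt$samples$treatment, pt$samples$tc, sep = ":")
  counts <- t(apply(pres, 2, function(x) tapply(x, cond, sum)))
  out <- data.frame(fraction = colnames(pt$normalized),
                    class = ifelse(rate >= min_presence, "continuous",
                                   "dichotomous"),
                    presence_rate = as.numeric(rate),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts))
}

#' Mixed linear model for continuous metabolite fractions
#'
#' Fits, per continuous fraction, the model
#' `log2(fraction) ~ Exp + Trt + TC + Trt:TC` with a random intercept for the
#' biological replicate pool (`run:replicate`), on the normalized areas.
#' Zero values cannot be log-transformed and are excluded with a logged
#' count. F-tests (marginal) are reported for Trt, TC and Trt x TC, plus
#' treatment-contrast coefficient estimates; per treatment x TC cell means
#' are tested against the grand mean with Tukey-Kramer-adjusted pairwise
#' contrasts available via [tukey_contrasts()]. Singular or failed mixed fits
#' fall back to OLS and are recorded (`method`).
#'
#' @param pt a normalized `peak_table`.
#' @param partition output of [partition_metabolites()]; fractions classed
#'   dichotomous are never fitted.
#' @param min_per_level minimum samples per TC level for a fraction to be
#'   testable.
#' @return data.frame per fitted fraction: coefficients `beta_exp`,
#'   `beta_trt`, `beta_tc`, `beta_inter`; variance components; F and p for
#'   Trt, TC, Trt x TC; `n_used`, `n_zero_excluded`, `method`.
#' @export
fit_metabolite_model <- function(pt, partition = partition_metabolites(pt),
                                 min_per_level = 2L) {
  stopifnot(inherits(pt, "peak_table"), !is.null(pt$normalized))
  cont <- partition$fraction[partition$class == "continuous"]
  s <- pt$samples
  base <- data.frame(
    exp = factor(s$run),
    trt = factor(s$treatment, levels = unique(s$treatment)),
    tc = factor(s$tc, levels = c("C", "T")),
    pool = paste(s$run, s$replicate, sep = ":"),
    stringsAsFactors = FALSE)
  rows <- lapply(cont, function(f) {
    v <- pt$normalized[, f]
    d <- base
    d$y <- log2(ifelse(v > 0, v, NA))
    n_zero <- sum(v <= 0)
    d <- d[!is.na(d$y), , drop = FALSE]
    out <- data.frame(fraction = f, n_used = nrow(d), n_zero_excluded = n_zero,
                      method = NA_character_, sigma2 = NA_real_,
                      sigma2_b = NA_real_, beta_exp = NA_real_,
                      beta_trt = NA_real_, beta_tc = NA_real_,
                      beta_inter = NA_real_, F_trt = NA_real_,
                      p_trt = NA_real_, F_tc = NA_real_, p_tc = NA_real_,
                      F_inter = NA_real_, p_inter = NA_real_,
                      stringsAsFactors = FALSE)
    if (min(table(d$tc)) < min_per_level || nlevels(droplevels(d$trt)) < 2 ||
        nlevels(droplevels(d$tc)) < 2) {
      out$method <- "untestable"
      return(out)
    }
    d$exp <- droplevels(d$exp)
    has_exp <- nlevels(d$exp) >= 2      # single-run subsets drop the term
    form <- if (has_exp) y ~ exp + trt + tc + trt:tc
    else y ~ trt + tc + trt:tc
    fit <- tryCatch(
      nlme::lme(form, random = ~ 1 | pool, data = d,
                na.action = stats::na.omit,
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      an <- tryCatch(stats::anova(fit, type = "marginal"),
                     error = function(e) NULL)
    } else an <- NULL
    if (!is.null(fit) && !is.null(an)) {
      out$method <- "lme"
      cf <- nlme::fixef(fit)
      vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)[, "Variance"]))
      out$sigma2 <- fit$sigma^2
      out$sigma2_b <- vc[1]
      pick_cf <- function(pat) {
        i <- grep(pat, names(cf))
        if (length(i) == 1) unname(cf[i]) else NA_real_
      }
      out$beta_exp <- pick_cf("^exp")
      out$beta_trt <- pick_cf("^trt[^:]*$")
      out$beta_tc <- pick_cf("^tc")
      out$beta_inter <- pick_cf(":")
      pick <- function(term, col) if (term %in% rownames(an))
        an[term, col] else NA_real_
      out$F_trt <- pick("trt", "F-value"); out$p_trt <- pick("trt", "p-value")
      out$F_tc <- pick("tc", "F-value"); out$p_tc <- pick("tc", "p-value")
      out$F_inter <- pick("trt:tc", "F-value")
      out$p_inter <- pick("trt:tc", "p-value")
    } else {
      out$method <- "ols"
      full <- stats::lm(form, data = d)
      cf <- stats::coef(full)
      out$sigma2 <- summary(full)$sigma^2
      out$sigma2_b <- 0
      pick_cf <- function(pat) {
        i <- grep(pat, names(cf))
        if (length(i) >= 1 && !is.na(cf[i[1]])) unname(cf[i[1]]) else NA_real_
      }
      out$beta_exp <- if (has_exp) pick_cf("^exp") else NA_real_
      out$beta_trt <- pick_cf("^trt[^:]*$")
      out$beta_tc <- pick_cf("^tc")
      out$beta_inter <- pick_cf(":")
      ex <- if (has_exp) "exp" else NULL
      cmp <- function(t0, t1) {
        a <- tryCatch(stats::anova(
          stats::lm(stats::reformulate(c(ex, t0), "y"), data = d),
          stats::lm(stats::reformulate(c(ex, t1), "y"), data = d)),
          error = function(e) NULL)
        if (is.null(a) || nrow(a) < 2) c(NA_real_, NA_real_)
        else c(a$F[2], a$`Pr(>F)`[2])
      }
      v <- cmp(c("trt", "tc"), c("trt", "tc", "trt:tc"))
      out$F_inter <- v[1]; out$p_inter <- v[2]
      v <- cmp("tc", c("trt", "tc"))
      out$F_trt <- v[1]; out$p_trt <- v[2]
      v <- cmp("trt", c("trt", "tc"))
      out$F_tc <- v[1]; out$p_tc <- v[2]
    }
    out
  })
  if (!length(rows))
    return(data.frame(fraction = character(), n_used = integer(),
                      n_zero_excluded = integer(), method = character(),
                      sigma2 = numeric(), sigma2_b = numeric(),
                      beta_exp = numeric(), beta_trt = numeric(),
                      beta_tc = numeric(), beta_inter = numeric(),
                      F_trt = numeric(), p_trt = numeric(),
                      F_tc = numeric(), p_tc = numeric(),
                      F_inter = numeric(), p_inter = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
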