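#' Filter spots by flag, spot class and background-relative intensity
#'
#' Applies the three spot-level exclusion rules used for two-color arrays of
#' this design, per array:
#' \enumerate{
#'   \item spots flagged bad (dust, abnormal shape, high local background) are
#'     discarded;
#'   \item non-experimental spot classes (spikes, poly(dA), blanks, buffer,
#'     negative controls) are discarded;
#'   \item spots whose background-subtracted median signal falls below the
#'     background-derived threshold in \emph{both} channels are discarded.
#' }
#' The threshold is computed per array and channel over all printed spots
#' (controls included) \emph{before} any removal. Two readings of the
#' "60% + 2 SD above overall background" rule are provided:
#' `"sixty_pct_of_mean_plus_2sd"` (default) fails a channel when
#' `foreground - background < 0.6 * (mean(bg) + 2 * sd(bg))`;
#' `"mean_plus_2sd"` fails when it is below `mean(bg) + 2 * sd(bg)`.
#'
#' @param spots long spot table (see [generate_array_experiment()] /
#'   [read_spot_table()]).
#' @param bg_rule threshold variant, see above.
#' @return list with `kept` (surviving experimental spots) and `rejected`
#'   (`array_id`, `probe_id`, `reason` in `flag`, `control_class`,
#'   `intensity`).
#' @export
filter_spots <- function(spots,
                         bg_rule = c("sixty_pct_of_mean_plus_2sd",
                                     "mean_plus_2sd")) {
  bg_rule <- match.arg(bg_rule)
  if (is.null(spots) || nrow(spots) == 0)
    stop("filter_spots: empty spot table", call. = FALSE)
  need <- c("array_id", "probe_id", "spot_class", "f_treat", "b_treat",
            "f_ctrl", "b_ctrl", "flag")
  missing_cols <- setdiff(need, names(spots))
  if (length(missing_cols))
    stop("filter_spots: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  # thresholds per array/channel over ALL spots, before removals
  thr <- do.call(rbind, lapply(split(spots, spots$array_id), function(s) {
    data.frame(array_id = s$array_id[1],
               thr_treat = mean(s$b_treat) + 2 * stats::sd(s$b_treat),
               thr_ctrl = mean(s$b_ctrl) + 2 * stats::sd(s$b_ctrl))
  }))
  mult <- if (bg_rule == "sixty_pct_of_mean_plus_2sd") 0.6 else 1
  idx <- match(spots$array_id, thr$array_id)

  reason <- rep(NA_character_, nrow(spots))
  reason[spots$flag == "bad"] <- "flag"
  is_ctrl <- spots$spot_class != "experimental"
  reason[is.na(reason) & is_ctrl] <- "control_class"
  fail_t <- (spots$f_treat - spots$b_treat) < mult * thr$thr_treat[idx]
  fail_c <- (spots$f_ctrl - spots$b_ctrl) < mult * thr$thr_ctrl[idx]
  reason[is.na(reason) & fail_t & fail_c] <- "intensity"

  kept <- spots[is.na(reason), , drop = FALSE]
  rejected <- data.frame(array_id = spots$array_id[!is.na(reason)],
                         probe_id = spots$probe_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Background-subtract, log2-transform and globally normalize ratios
#'
#' Per spot, the treated/control ratio is
#' `(f_treat - b_treat) / (f_ctrl - b_ctrl)` converted to log2. Spots with a
#' non-positive background-subtracted signal in either channel cannot be
#' log-transformed and are dropped with reason `"nonpositive"`. Global
#' normalization then centers each array's log-ratios on zero (single-factor
#' normalization, removing array-wide dye and hybridization bias); it is
#' idempotent. Arrays with fewer than `min_spots` usable spots are excluded
#' with a warning.
#'
#' @param kept filtered spot table (the `kept` element of [filter_spots()]).
#' @param normalize center each array (default `TRUE`).
#' @param min_spots minimum usable spots for an array to be retained.
#' @return list with `log_ratios` (`probe_id`, `array_id`, `log_ratio`),
#'   `rejected` (nonpositive-signal spots) and `excluded_arrays`.
#' @export
compute_log_ratios <- function(kept, normalize = TRUE, min_spots = 10L) {
  if (is.null(kept) || nrow(kept) == 0)
    stop("compute_log_ratios: no spots", call. = FALSE)
  s_t <- kept$f_treat - kept$b_treat
  s_c <- kept$f_ctrl - kept$b_ctrl
  bad <- s_t <= 0 | s_c <= 0
  rejected <- data.frame(array_id = kept$array_id[bad],
                         probe_id = kept$probe_id[bad],
                         reason = rep("nonpositive", sum(bad)),
                         stringsAsFactors = FALSE)
  lr <- data.frame(probe_id = kept$probe_id[!bad],
                   array_id = kept$array_id[!bad],
                   log_ratio = log2(s_t[!bad] / s_c[!bad]),
                   stringsAsFactors = FALSE)
  n_per <- table(lr$array_id)
  excluded <- names(n_per)[n_per < min_spots]
  if (length(excluded)) {
    warning("excluding array(s) with < ", min_spots, " usable spots: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    lr <- lr[!lr$array_id %in% excluded, , drop = FALSE]
  }
  if (normalize && nrow(lr) > 0)
    lr$log_ratio <- lr$log_ratio -
      stats::ave(lr$log_ratio, lr$array_id, FUN = mean)
  rownames(lr) <- NULL
  list(log_ratios = lr, rejected = rejected, excluded_arrays = excluded)
}

#' Collapse duplicated probes to one value per probe and array
#'
#' Probes printed more than once on an array are replaced by the arithmetic
#' mean of their log-ratios (means taken on the log scale, where the analysis
#' operates).
#'
#' @param lr log-ratio table (`probe_id`, `array_id`, `log_ratio`).
#' @return log-ratio table with at most one row per (probe, array).
#' @export
collapse_duplicates <- function(lr) {
  if (nrow(lr) == 0) return(lr)
  agg <- stats::aggregate(log_ratio ~ probe_id + array_id, data = lr,
                          FUN = mean)
  agg <- agg[order(agg$array_id, agg$probe_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Box-Cox symmetry diagnostic
#'
#' Profiles the Box-Cox log-likelihood of a location model over a grid of
#' power parameters and reports the maximizing lambda, a 95% likelihood-ratio
#' confidence interval (chi-square(1) cutoff), and a transformation
#' recommendation: `"log"` when the interval contains 0, `"identity"` when it
#' contains 1 (log wins when both), otherwise `"other"`. This reproduces the
#' check that motivates analysing two-channel intensities as log2 ratios.
#'
#' @param values positive measurements (n >= 10).
#' @param grid lambda grid (default `seq(-2, 2, by = 0.05)`).
#' @param conf confidence level for the LR interval.
#' @return list of class `boxcox_result`: `lambda_hat`, `ci95`,
#'   `recommendation`, `grid`, `loglik`.
#' @export
boxcox_symmetry <- function(values, grid = seq(-2, 2, by = 0.05),
                            conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 10)
    stop("boxcox_symmetry: need at least 10 values", call. = FALSE)
  if (any(values <= 0))
    stop("boxcox_symmetry: all values must be positive", call. = FALSE)
  ll <- vapply(grid, boxcox_loglik, numeric(1), y = values)
  lambda_hat <- grid[which.max(ll)]
  cutoff <- max(ll) - stats::qchisq(conf, df = 1) / 2
  in_ci <- grid[ll >= cutoff]
  ci <- range(in_ci)
  recommendation <- if (ci[1] <= 0 && ci[2] >= 0) "log"
  else if (ci[1] <= 1 && ci[2] >= 1) "identity"
  else "other"
  structure(list(lambda_hat = lambda_hat, ci95 = ci,
                 recommendation = recommendation, grid = grid, loglik = ll),
            class = "boxcox_result")
}

# Profile log-likelihood of the Box-Cox transform for a pure location model:
# -n/2 log(sigma_hat^2(lambda)) + (lambda - 1) sum(log y)
boxcox_loglik <- function(lambda, y) {
  n <- length(y)
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  s2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}
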