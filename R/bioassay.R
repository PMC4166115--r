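#' Colony-forming units per cm2 of leaf area
#'
#' Back-calculates bacterial density from a plate count: leaf disks (cut with
#' a cork borer, default diameter 6.25 mm) are ground in extraction buffer, a
#' dilution is plated, and colonies counted. Then
#' `CFU/cm2 = count * dilution * (extract_volume / plated_volume) / area`,
#' with `area = n_disks * pi * (diameter_mm / 20)^2` cm2.
#'
#' @param colony_count colonies counted on the plate.
#' @param dilution_factor total dilution of the plated suspension.
#' @param plated_volume_ul volume plated (microliters).
#' @param extract_volume_ul total extract volume (microliters).
#' @param n_disks number of leaf disks pooled in the extract.
#' @param disk_diameter_mm cork-borer diameter (mm).
#' @return CFU per cm2 of leaf area (vectorized).
#' @export
cfu_per_cm2 <- function(colony_count, dilution_factor, plated_volume_ul,
                        extract_volume_ul, n_disks = 1,
                        disk_diameter_mm = 6.25) {
  if (any(plated_volume_ul <= 0) || any(extract_volume_ul <= 0))
    stop("cfu_per_cm2: volumes must be positive", call. = FALSE)
  if (any(n_disks <= 0) || any(disk_diameter_mm <= 0))
    stop("cfu_per_cm2: disk count and diameter must be positive",
         call. = FALSE)
  if (any(colony_count < 0) || any(dilution_factor <= 0))
    stop("cfu_per_cm2: counts must be >= 0 and dilution > 0", call. = FALSE)
  area_cm2 <- n_disks * pi * (disk_diameter_mm / 20)^2
  colony_count * dilution_factor * (extract_volume_ul / plated_volume_ul) /
    area_cm2
}

#' Relative expression from qPCR CT values (delta-delta-CT)
#'
#' Per sample, `dCT = CT(target) - CT(reference)` (here PR1 against 18S);
#' between conditions, `ddCT = dCT(treated) - dCT(control)` and the
#' treatment/control fold change is `2^(-ddCT)`. Adding a constant to both CT
#' channels of a sample leaves the result unchanged.
#'
#' @param ct_target_treated,ct_ref_treated CT values in the treated sample.
#' @param ct_target_control,ct_ref_control CT values in the control sample.
#' @return fold change (treated relative to control), vectorized.
#' @export
relative_expression <- function(ct_target_treated, ct_ref_treated,
                                ct_target_control, ct_ref_control) {
  args <- list(ct_target_treated, ct_ref_treated, ct_target_control,
               ct_ref_control)
  if (any(vapply(args, function(x) any(!is.finite(x)), logical(1))))
    stop("relative_expression: CT values must be finite (missing partner?)",
         call. = FALSE)
  dct_t <- ct_target_treated - ct_ref_treated
  dct_c <- ct_target_control - ct_ref_control
  2^(-(dct_t - dct_c))
}

#' Two-group comparison (Welch's t-test)
#'
#' The significance test used for the bioassay group comparisons. Welch's
#' unequal-variance two-sample t-test is an implementation choice (the
#' original analysis does not name its test). The degenerate case of two
#' constant, equal groups returns p = 1.
#'
#' @param values_a,values_b numeric observations per group (>= 2 each).
#' @param alpha significance level for the flag.
#' @return list: `statistic`, `df`, `p_value`, `significant`, `mean_a`,
#'   `mean_b`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("compare_groups: need at least two values per group", call. = FALSE)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    equal <- mean(values_a) == mean(values_b)
    return(list(statistic = if (equal) 0 else Inf,
                df = NA_real_, p_value = if (equal) 1 else 0,
                significant = !equal, mean_a = mean(values_a),
                mean_b = mean(values_b)))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       mean_a = mean(values_a), mean_b = mean(values_b))
}
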