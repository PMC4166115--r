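# Minimal hand-built peak table: 2 samples, 2 fractions, 2 standards.
tiny_peak_table <- function(areas, masses = c(15, 15),
                            frac_rt = c(F1 = 10, F2 = 30),
                            std_rt = c(8, 32),
                            std_areas = matrix(1, 2, 2)) {
  structure(list(
    samples = data.frame(sample_id = c("S1", "S2"), run = c(1, 1),
                         treatment = c("Psyr", "Psyr"), tc = c("T", "C"),
                         replicate = c(1, 2), sample_mass_mg = masses),
    areas = matrix(areas, 2, length(frac_rt),
                   dimnames = list(c("S1", "S2"), names(frac_rt))),
    fraction_rt = frac_rt,
    standards = data.frame(label = c("early", "late"), rt = std_rt),
    standard_areas = matrix(std_areas, 2, 2,
                            dimnames = list(c("S1", "S2"),
                                            c("early", "late")))),
    class = "peak_table")
}

test_that("normalization follows the mass / internal-standard arithmetic", {
  # one fraction, IS area equal to raw area, mass 15 -> adjusted 1/15,
  # normalized to 100 at the per-fraction max
  pt <- tiny_peak_table(areas = c(45, 90, 30, 60), masses = c(15, 15),
                        std_areas = cbind(c(45, 90), c(45, 90)))
  pt <- normalize_peak_areas(pt)
  expect_equal(unname(pt$adjusted[, "F1"]), c(1 / 15, 1 / 15))
  expect_equal(unname(pt$normalized[, "F1"]), c(100, 100))

  # adjusted values {2, 4} -> normalized {50, 100}
  pt2 <- tiny_peak_table(areas = c(2, 4, 2, 4), masses = c(1, 1),
                         std_areas = matrix(1, 2, 2))
  pt2 <- normalize_peak_areas(pt2)
  expect_equal(unname(pt2$normalized[, "F1"]), c(50, 100))

  # sample-total variant sums to 100 per sample
  pt3 <- normalize_peak_areas(pt2, scale = "sample_total")
  expect_equal(unname(rowSums(pt3$normalized)), c(100, 100))
})

test_that("internal-standard matching is by retention time, earlier on tie", {
  # F1 at rt 10 -> early std (|10-8| < |10-32|); Fmid exactly midway -> early
  pt <- tiny_peak_table(areas = c(10, 10, 10, 10),
                        frac_rt = c(F1 = 10, Fmid = 20),
                        std_rt = c(8, 32),
                        std_areas = cbind(c(2, 2), c(5, 5)))
  pt$fraction_rt <- c(F1 = 10, Fmid = 20)
  names(pt$fraction_rt) <- colnames(pt$areas) <- c("F1", "Fmid")
  pt <- normalize_peak_areas(pt)
  expect_equal(unname(pt$adjusted[1, "F1"]), 10 / 15 / 2)
  expect_equal(unname(pt$adjusted[1, "Fmid"]), 10 / 15 / 2)  # early std wins

  pt_bad <- tiny_peak_table(areas = rep(1, 4),
                            std_areas = cbind(c(0, 1), c(1, 1)))
  expect_error(normalize_peak_areas(pt_bad), "S1")
})

test_that("normalization is scale-invariant per fraction", {
  pt <- generate_metabolite_experiment(metab_design(seed = 77L))
  n1 <- normalize_peak_areas(pt)$normalized
  pt$areas[, "F05"] <- pt$areas[, "F05"] * 37.5
  n2 <- normalize_peak_areas(pt)$normalized
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("partition separates continuous from condition-restricted", {
  pt <- normalize_peak_areas(generate_metabolite_experiment())
  part <- partition_metabolites(pt)
  truth <- pt$truth
  expect_equal(part$class[match(truth$fraction, part$fraction)], truth$class)
  # fully-present fraction is continuous
  full <- part$fraction[part$presence_rate == 1]
  expect_true(all(part$class[part$fraction %in% full] == "continuous"))
  # camalexin-like: present only in pathogen-treated samples -> dichotomous
  dich <- truth$fraction[truth$present_in != "all"]
  expect_true(all(part$class[part$fraction %in% dich] == "dichotomous"))

  # threshold sweep moves fractions monotonically toward dichotomous
  n_cont <- vapply(seq(0.5, 1.0, by = 0.1), function(th)
    sum(partition_metabolites(pt, min_presence = th)$class == "continuous"),
    numeric(1))
  expect_true(all(diff(n_cont) <= 0))
})

test_that("planted TC effect is recovered exactly in the noise-free limit", {
  spec <- metab_design(frac_dichotomous = 0, frac_affected = 0.3,
                       sd_noise = 0, sd_pool = 0, seed = 99L)
  pt <- normalize_peak_areas(generate_metabolite_experiment(spec))
  part <- partition_metabolites(pt)
  # zero-residual data sits on the optimizer boundary; warnings expected
  fits <- suppressWarnings(fit_metabolite_model(pt, part))
  aff <- pt$truth$fraction[pt$truth$beta_tc != 0]
  got <- fits$beta_tc[match(aff, fits$fraction)]
  expect_equal(got, pt$truth$beta_tc[pt$truth$fraction %in% aff],
               tolerance = 1e-6)
  # unaffected fractions estimate ~ 0
  null <- fits$beta_tc[!(fits$fraction %in% aff)]
  expect_lt(max(abs(null)), 1e-6)
})

test_that("all-equal samples give zero effects and no significance", {
  pt <- tiny_peak_table(areas = rep(8, 4), std_areas = matrix(1, 2, 2))
  pt$samples <- rbind(pt$samples, pt$samples, pt$samples, pt$samples)
  pt$samples$sample_id <- sprintf("S%d", 1:8)
  pt$samples$tc <- rep(c("T", "C"), 4)
  pt$samples$treatment <- rep(c("Psyr", "Spod"), each = 4)
  pt$samples$replicate <- rep(1:2, each = 2, times = 2)
  pt$samples$run <- 1
  pt$areas <- matrix(8, 8, 2, dimnames = list(pt$samples$sample_id,
                                              c("F1", "F2")))
  pt$standard_areas <- matrix(1, 8, 2,
                              dimnames = list(pt$samples$sample_id,
                                              c("early", "late")))
  pt$samples$sample_mass_mg <- 1
  pt <- normalize_peak_areas(pt)
  fits <- fit_metabolite_model(pt, partition_metabolites(pt))
  expect_true(all(abs(fits$beta_tc) < 1e-10))
  expect_true(all(abs(fits$beta_trt) < 1e-10))
  expect_false(any(isTRUE(fits$p_tc < 0.05)))
})

test_that("zero pool variance reduces to the OLS oracle", {
  spec <- metab_design(frac_dichotomous = 0, sd_pool = 0, seed = 101L)
  pt <- normalize_peak_areas(generate_metabolite_experiment(spec))
  fits <- fit_metabolite_model(pt, partition_metabolites(pt))
  f <- fits$fraction[1]
  d <- data.frame(y = log2(pt$normalized[, f]),
                  exp = factor(pt$samples$run),
                  trt = factor(pt$samples$treatment),
                  tc = factor(pt$samples$tc, levels = c("C", "T")))
  ols <- lm(y ~ exp + trt + tc + trt:tc, data = d)
  expect_equal(fits$beta_tc[1], unname(coef(ols)["tcT"]), tolerance = 1e-4)
})

test_that("dichotomous fractions never enter the mixed model", {
  pt <- normalize_peak_areas(generate_metabolite_experiment())
  part <- partition_metabolites(pt)
  fits <- fit_metabolite_model(pt, part)
  dich <- part$fraction[part$class == "dichotomous"]
  expect_gt(length(dich), 0)
  expect_false(any(fits$fraction %in% dich))
  # presence counts exist for every condition
  expect_true(all(c("Psyr:T", "Psyr:C", "Spod:T", "Spod:C") %in% names(part)))
})
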