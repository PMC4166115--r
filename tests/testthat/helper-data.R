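# Shared fixture builders (all generated in code; nothing on disk).

# A small design that keeps pipeline-level tests fast.
small_design <- function(...) {
  array_design(n_probes = 120L, n_duplicated = 4L, n_reps = 2L,
               control_classes = c(spike = 3L, polyA = 1L, blank = 2L,
                                   buffer = 1L, negative = 2L),
               seed = 42L, ...)
}

quiet_effects <- function(...) {
  effect_spec(missing_rate = 0, ...)
}

# Hand-built long spot table; backgrounds fixed so the filter threshold can be
# recomputed independently in tests.
toy_spots <- function() {
  set.seed(7)
  n <- 10
  data.frame(
    array_id = "T1",
    probe_id = sprintf("P%02d", 1:n),
    spot_class = "experimental",
    f_treat = c(5000, 4000, 120, 90, 3000, 150, 2500, 80, 95, 6000),
    b_treat = c(100, 110, 95, 85, 105, 100, 90, 75, 90, 115),
    f_ctrl = c(4500, 3800, 110, 100, 2800, 2000, 130, 85, 100, 5500),
    b_ctrl = c(95, 105, 100, 95, 100, 110, 95, 80, 95, 105),
    flag = "good", stringsAsFactors = FALSE)
}

# Residual table realising an exact per-probe 6-vector over a balanced
# complete-block design (no noise).
exact_residuals <- function(truth_vec, samples,
                            cells = c("Psyr_1", "Psyr_6", "Psyr_24",
                                      "Spod_1", "Spod_6", "Spod_24")) {
  stopifnot(length(truth_vec) == length(cells))
  names(truth_vec) <- cells
  cell <- paste(samples$treatment, samples$time_h, sep = "_")
  data.frame(probe_id = "PX", array_id = samples$array_id,
             residual = as.numeric(truth_vec[cell]),
             stringsAsFactors = FALSE)
}
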