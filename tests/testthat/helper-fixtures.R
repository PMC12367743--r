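# Shared fixtures: small, fast cohort designs built in code.

# 4-patient, 60-gene design with a single 10-gene module shifted -2 in
# survivors; arm and outcome aligned (both TC patients deceased).
tiny_design <- function(seed = 1L, noise_sd = 0, effect = -2,
                        deceased_effect = 0) {
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    arm = c("BRT", "BRT", "TC", "TC"),
    outcome = c("survivor", "survivor", "deceased", "deceased"),
    batch = c("b1", "b1", "b2", "b2"),
    stringsAsFactors = FALSE)
  cohort_design(
    patients = patients, n_genes = 60L,
    modules = list(mod = 10L),
    effect_sizes = list(mod = c(survivor = effect, deceased = deceased_effect)),
    batch_offsets = c(b1 = 0, b2 = 0),
    noise_sd = noise_sd, baseline_mean_sd = c(8, 2), seed = seed)
}

# zero-everything null design used by calibration tests
null_design <- function(seed, n_genes = 200L, noise_sd = 0.5) {
  d <- tiny_design(seed = seed, noise_sd = noise_sd, effect = 0)
  d$n_genes <- as.integer(n_genes)
  d
}

# deterministic toy expression matrix with named dims
toy_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), dimnames = list(genes, samples))
}

toy_meta <- function(patients, arms = NULL, outcomes = NULL, batches = NULL) {
  n <- length(patients)
  data.frame(
    sample_id = c(paste0(patients, "_pre"), paste0(patients, "_post")),
    patient_id = rep(patients, 2),
    timepoint = rep(c("pre", "post"), each = n),
    arm = rep(arms %||% rep("BRT", n), 2),
    outcome = rep(outcomes %||% rep("survivor", n), 2),
    batch = rep(batches %||% rep("b1", n), 2),
    stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
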