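# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: paired
# pre/post log2 expression per patient, planted outcome-linked gene modules
# (type I/II/III interferon, B cell, coagulation), additive batch offsets,
# and Gaussian log-scale noise — plus matching clinical and survival tables.
# Expression is drawn directly on the log2 scale; fold changes and z-scores
# are log-scale constructs, so a Gaussian log-scale model carries all the
# structure the pipeline consumes. `expression_counts()` converts to
# pseudo-counts for I/O exercises.

#' Construct a synthetic cohort design
#'
#' @param patients data.frame with columns patient_id, arm ("BRT"/"TC"),
#'   outcome ("survivor"/"deceased"), batch.
#' @param n_genes total number of genes; module genes are assigned to
#'   disjoint index ranges from the front unless explicit `genes` are given.
#' @param modules named list; each element is either an integer size or a
#'   list with `size`, optional `signs` (+1/-1 vector of that size) and
#'   optional explicit `genes` (integer indices into 1..n_genes).
#' @param effect_sizes named list: module -> named numeric
#'   c(survivor = ..., deceased = ...), the log2 shift added to post-treatment
#'   samples of that outcome (multiplied per gene by the module sign).
#' @param batch_offsets named numeric: batch label -> additive log2 offset.
#' @param noise_sd log2-scale Gaussian noise sd (>= 0).
#' @param baseline_mean_sd length-2 numeric (mu0, sigma0) for genewise
#'   baseline means.
#' @param typeI_responders patient ids among the deceased that receive the
#'   type I interferon shift; the type I rise is not universal in fatal
#'   disease, so it is configurable per patient (default: the first deceased
#'   patient).
#' @param seed integer seed; identical (design, seed) gives bit-identical
#'   cohorts.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(patients, n_genes, modules, effect_sizes,
                          batch_offsets, noise_sd = 0.5,
                          baseline_mean_sd = c(8, 2),
                          typeI_responders = NULL, seed = 1L) {
  if (anyDuplicated(patients$patient_id))
    stop2("duplicate patient_id in design")
  if (!all(patients$outcome %in% c("survivor", "deceased")))
    stop2("outcome must be 'survivor' or 'deceased'")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  modules <- lapply(modules, function(m) {
    if (is.numeric(m) && length(m) == 1) m <- list(size = as.integer(m))
    if (is.null(m$signs)) m$signs <- rep(1, m$size)
    if (length(m$signs) != m$size || !all(m$signs %in% c(-1, 1)))
      stop2("module signs must be +1/-1 of length size")
    m
  })
  # assign disjoint gene index ranges; explicit ranges are honoured and
  # checked for overlap
  cursor <- 1L
  taken <- integer(0)
  for (nm in names(modules)) {
    m <- modules[[nm]]
    if (is.null(m$genes)) {
      m$genes <- seq.int(cursor, cursor + m$size - 1L)
      cursor <- cursor + m$size
    }
    if (length(intersect(m$genes, taken)))
      stop2("overlapping module definitions: '", nm, "'")
    taken <- c(taken, m$genes)
    modules[[nm]] <- m
  }
  if (length(taken) > n_genes || max(taken) > n_genes)
    stop2("module gene counts exceed n_genes")
  if (is.null(typeI_responders) && "typeI" %in% names(modules)) {
    dec <- patients$patient_id[patients$outcome == "deceased"]
    typeI_responders <- utils::head(dec, 1)
  }
  structure(list(patients = patients, n_genes = as.integer(n_genes),
                 modules = modules, effect_sizes = effect_sizes,
                 batch_offsets = batch_offsets, noise_sd = noise_sd,
                 baseline_mean_sd = baseline_mean_sd,
                 typeI_responders = typeI_responders,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default six-patient study design
#'
#' Two treatment arms of three patients each (two of the TC arm deceased),
#' one sequencing batch per arm, and planted modules sized to the three
#' interferon signatures (type I: 73 genes, type II: 94, type III: 10) plus
#' B-cell (100) and coagulation (50) modules.
#'
#' Default planted log2 effects on post-treatment samples: survivors get -2
#' on all interferon modules and the B-cell module (treatment suppresses
#' interferon and B-cell programs); deceased patients get +2 on type II and
#' type III interferon and on coagulation, and +2 on type I for the
#' configured responder subset (default: one of the two deceased patients).
#' Noise sd 0.5 log2 units; batch offsets 0 (BRT batch) and +0.5 (TC batch).
#'
#' @param seed integer seed stored in the design.
#' @param noise_sd log2 noise sd override.
#' @param effect magnitude of the planted shifts (default 2 log2 units).
#' @return a `cohort_design`.
#' @export
default_study_design <- function(seed = 1L, noise_sd = 0.5, effect = 2) {
  patients <- data.frame(
    patient_id = c("TC-1", "TC-2", "TC-3", "BRT-1", "BRT-2", "BRT-3"),
    arm = c("TC", "TC", "TC", "BRT", "BRT", "BRT"),
    outcome = c("deceased", "survivor", "deceased",
                "survivor", "survivor", "survivor"),
    batch = c("batch_TC", "batch_TC", "batch_TC",
              "batch_BRT", "batch_BRT", "batch_BRT"),
    stringsAsFactors = FALSE)
  cohort_design(
    patients = patients,
    n_genes = 1000L,
    modules = list(typeI = 73L, typeII = 94L, typeIII = 10L,
                   bcell = 100L, coagulation = 50L),
    effect_sizes = list(
      typeI       = c(survivor = -effect, deceased = effect),
      typeII      = c(survivor = -effect, deceased = effect),
      typeIII     = c(survivor = -effect, deceased = effect),
      bcell       = c(survivor = -effect, deceased = 0),
      coagulation = c(survivor = 0,       deceased = effect)),
    batch_offsets = c(batch_BRT = 0, batch_TC = 0.5),
    noise_sd = noise_sd,
    baseline_mean_sd = c(8, 2),
    seed = seed)
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic cohort from a design
#'
#' Expression for gene g in sample s is
#' `baseline_g + batch_offset(batch(s)) + planted(g, s) + N(0, noise_sd)`,
#' where `planted` is the module's signed effect on post-treatment samples
#' of the matching outcome (type I applies only to the configured deceased
#' responders). Deceased patients get an event time uniform on (2, 3)
#' months — sampling happens shortly before death — and survivors are
#' censored at 12 months.
#'
#' @param design a `cohort_design`.
#' @return object of class `synthetic_cohort`: list with `expression`
#'   (genes x samples log2 matrix), `metadata`, `gene_sets`
#'   (`gene_set_collection` of the planted modules), `clinical`, `survival`
#'   and the `design`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  p <- design$patients
  n_pat <- nrow(p)
  gene_ids <- sprintf("G%04d", seq_len(design$n_genes))
  sample_ids <- c(paste0(p$patient_id, "_pre"), paste0(p$patient_id, "_post"))
  meta <- data.frame(
    sample_id = sample_ids,
    patient_id = rep(p$patient_id, 2),
    timepoint = rep(c("pre", "post"), each = n_pat),
    arm = rep(p$arm, 2),
    outcome = rep(p$outcome, 2),
    batch = rep(p$batch, 2),
    stringsAsFactors = FALSE)

  with_seed(design$seed, {
    baseline <- stats::rnorm(design$n_genes, design$baseline_mean_sd[1],
                             design$baseline_mean_sd[2])
    planted <- matrix(0, design$n_genes, 2 * n_pat)
    for (nm in names(design$modules)) {
      m <- design$modules[[nm]]
      eff <- design$effect_sizes[[nm]]
      if (is.null(eff)) next
      post_cols <- which(meta$timepoint == "post")
      for (j in post_cols) {
        out <- meta$outcome[j]
        e <- unname(eff[out])
        if (is.na(e) || e == 0) next
        if (nm == "typeI" && out == "deceased" &&
            !(meta$patient_id[j] %in% design$typeI_responders)) next
        planted[m$genes, j] <- planted[m$genes, j] + m$signs * e
      }
    }
    offsets <- design$batch_offsets[meta$batch]
    offsets[is.na(offsets)] <- 0
    noise <- matrix(stats::rnorm(design$n_genes * 2 * n_pat, 0, design$noise_sd),
                    design$n_genes, 2 * n_pat)
    expr <- baseline + planted + noise
    expr <- expr + rep(offsets, each = design$n_genes)
    dimnames(expr) <- list(gene_ids, sample_ids)

    # clinical covariates: deceased patients skew older with more risk factors
    age <- round(stats::rnorm(n_pat, ifelse(p$outcome == "deceased", 62, 50), 8))
    risk <- pmin(6L, pmax(3L, stats::rpois(n_pat, 4) +
                            as.integer(p$outcome == "deceased")))
    clinical <- data.frame(
      patient_id = p$patient_id, arm = p$arm, outcome = p$outcome,
      age = age, risk_factors = risk,
      sex = sample(c("F", "M"), n_pat, replace = TRUE, prob = c(0.8, 0.2)),
      ssa_positive = stats::rbinom(n_pat, 1, 0.2),
      heliotrope = stats::rbinom(n_pat, 1, 0.4),
      arthritis = stats::rbinom(n_pat, 1, 0.3),
      stringsAsFactors = FALSE)
    survival <- data.frame(
      patient_id = p$patient_id,
      arm = p$arm,
      time_months = ifelse(p$outcome == "deceased",
                           stats::runif(n_pat, 2, 3), 12),
      event = as.integer(p$outcome == "deceased"),
      stringsAsFactors = FALSE)

    sets <- lapply(design$modules, function(m) gene_ids[m$genes])
    signs <- unlist(lapply(design$modules, function(m) {
      s <- m$signs
      names(s) <- gene_ids[m$genes]
      s[s == -1]
    }), use.names = TRUE)
    if (length(signs)) names(signs) <- sub("^[^.]+\\.", "", names(signs))
    gene_sets <- new_gene_set_collection(sets, signs)

    validate_expression(expr)
    validate_metadata(meta, expr)
    structure(list(expression = expr, metadata = meta, gene_sets = gene_sets,
                   clinical = clinical, survival = survival, design = design),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;",
      nrow(x$design$patients), "patients;",
      length(x$gene_sets$sets), "planted modules\n")
  invisible(x)
}

#' Convert log2 expression to pseudo-counts
#'
#' `round(2^x)` per cell; provided for I/O exercises with count-based tools,
#' not used by the analysis itself.
#'
#' @param expr log2 expression matrix.
#' @return integer-valued matrix of the same shape.
#' @export
expression_counts <- function(expr) {
  round(2^expr)
}

#' Write all cohort components to a directory
#'
#' Emits expression.tsv, metadata.tsv, gene_sets.gmt (+ gene_signs.tsv when
#' any -1 coefficients exist), clinical.tsv and survival.tsv.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"),
            file.path(dir, "gene_signs.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_survival(cohort$survival, file.path(dir, "survival.tsv"))
  invisible(dir)
}
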