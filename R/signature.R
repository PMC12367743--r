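# Interferon signature scoring: batch mean-centering, genewise z-scoring
# across all scored samples (pre and post pooled), +1/-1 coefficients, and
# the signed z-score sum — plus per-patient pre/post score dynamics and the
# survivor-vs-deceased genewise fold-change comparison.

#' Batch mean-centering of an expression matrix
#'
#' Per gene and per batch, subtracts that batch's mean, removing additive
#' cohort offsets before pooled z-scoring. Single-batch input is returned
#' unchanged. Idempotent: centering twice equals centering once.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param meta sample metadata with a `batch` column bound to `expr`.
#' @return centered matrix of the same shape.
#' @export
batch_center <- function(expr, meta) {
  validate_expression(expr)
  validate_metadata(meta, expr)
  batches <- unique(meta$batch)
  if (length(batches) <= 1) return(expr)
  out <- expr
  for (b in batches) {
    cols <- meta$sample_id[meta$batch == b]
    out[, cols] <- expr[, cols, drop = FALSE] -
      rowMeans(expr[, cols, drop = FALSE])
  }
  out
}

#' Genewise z-scoring
#'
#' Each gene row is standardised to mean 0 and sample standard deviation 1
#' across all samples. The sd denominator is n-1 by default (`denominator =
#' "n"` for the population form, offered for sensitivity analysis).
#'
#' @param expr (typically batch-centered) expression matrix.
#' @param denominator "n-1" (default) or "n".
#' @return z-score matrix of the same shape.
#' @export
zscore_rows <- function(expr, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  validate_expression(expr)
  mu <- rowMeans(expr)
  sdv <- row_sds(expr)
  if (denominator == "n")
    sdv <- sdv * sqrt((ncol(expr) - 1) / ncol(expr))
  zero <- sdv == 0
  if (any(zero))
    stop2("zero-variance gene(s): ",
          paste(utils::head(rownames(expr)[zero], 5), collapse = ", "),
          if (sum(zero) > 5) sprintf(" (+%d more)", sum(zero) - 5) else "",
          "; prefilter before z-scoring")
  (expr - mu) / sdv
}

#' Signed-sum signature score per sample
#'
#' For each gene set, the score of sample s is `sum over set genes of
#' c_g * z(g, s)` with coefficients c_g = +1 (high expression) or -1 (low
#' expression). Set genes missing from the matrix are skipped with a warning
#' (gene-set/annotation mismatches are routine); an empty intersection is an
#' error.
#'
#' @param z z-score matrix from [zscore_rows()].
#' @param collection a `gene_set_collection` (signs default to +1).
#' @param sets optional subset of set names to score.
#' @return data.frame: sample_id, set_name, score.
#' @export
signature_score <- function(z, collection, sets = names(collection$sets)) {
  validate_expression(z)
  rows <- lapply(sets, function(nm) {
    genes <- collection$sets[[nm]]
    if (is.null(genes)) stop2("unknown set '", nm, "'")
    present <- intersect(genes, rownames(z))
    if (!length(present))
      stop2("set '", nm, "' has no genes in the matrix")
    if (length(present) < length(genes))
      warning(sprintf("set '%s': %d of %d genes missing from matrix, skipped",
                      nm, length(genes) - length(present), length(genes)),
              call. = FALSE)
    cg <- set_signs(collection, present)
    data.frame(sample_id = colnames(z), set_name = nm,
               score = as.numeric(crossprod(z[present, , drop = FALSE], cg)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Batch-center, z-score and score in one step
#'
#' The scoring population is all samples of all patients in the analysis,
#' pre and post pooled, so pre/post deltas live on a common scale.
#'
#' @inheritParams batch_center
#' @inheritParams signature_score
#' @inheritParams zscore_rows
#' @return data.frame as in [signature_score()].
#' @export
score_signatures <- function(expr, meta, collection,
                             sets = names(collection$sets),
                             denominator = "n-1") {
  centered <- batch_center(expr, meta)
  keep <- row_sds(centered) > 0
  z <- zscore_rows(centered[keep, , drop = FALSE], denominator = denominator)
  signature_score(z, collection, sets)
}

#' Per-patient signature score dynamics
#'
#' For every patient with both timepoints and every scored set: the pre and
#' post scores, their delta (post - pre) and a direction call, plus group
#' summaries by outcome.
#'
#' @param scores output of [signature_score()] / [score_signatures()].
#' @param meta sample metadata.
#' @param flat_tol |delta| below this is called "flat" (default 0).
#' @return list with `per_patient` (patient_id, set_name, outcome, pre,
#'   post, delta, direction) and `by_outcome` (set_name, outcome, mean and
#'   sd of delta, n).
#' @export
score_dynamics <- function(scores, meta, flat_tol = 0) {
  m <- merge(scores, meta[, c("sample_id", "patient_id", "timepoint", "outcome")],
             by = "sample_id")
  wide <- merge(
    m[m$timepoint == "pre", c("patient_id", "set_name", "outcome", "score")],
    m[m$timepoint == "post", c("patient_id", "set_name", "score")],
    by = c("patient_id", "set_name"), suffixes = c("_pre", "_post"))
  if (!nrow(wide)) stop2("no patient has both timepoints scored")
  wide$delta <- wide$score_post - wide$score_pre
  wide$direction <- ifelse(abs(wide$delta) <= flat_tol, "flat",
                           ifelse(wide$delta > 0, "up", "down"))
  per_patient <- data.frame(
    patient_id = wide$patient_id, set_name = wide$set_name,
    outcome = wide$outcome, pre = wide$score_pre, post = wide$score_post,
    delta = wide$delta, direction = wide$direction, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(per_patient, list(per_patient$set_name, per_patient$outcome),
          drop = TRUE),
    function(d) data.frame(set_name = d$set_name[1], outcome = d$outcome[1],
                           mean_delta = mean(d$delta), sd_delta = stats::sd(d$delta),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(per_patient = per_patient, by_outcome = agg)
}

#' Genewise fold-change comparison between outcome groups
#'
#' For each gene of a set, the group value is the mean per-patient log2 fold
#' change within the outcome group; the two gene-level distributions
#' (survivors vs deceased) are compared by Welch's two-sample t-test. The
#' unit of the test is the gene, matching violin-plot summaries of genewise
#' fold-change distributions.
#'
#' @param fc genes x patients log2 fold-change matrix.
#' @param meta sample metadata (patient outcome lookup).
#' @param genes character vector of set genes (>= 2 present in `fc`).
#' @return list with `t`, `dof`, `p_value`, group means/sds, and
#'   `gene_means` (per gene per group; plot-ready).
#' @export
compare_fc_by_outcome <- function(fc, meta, genes) {
  pat_out <- unique(meta[, c("patient_id", "outcome")])
  out <- stats::setNames(pat_out$outcome, pat_out$patient_id)[colnames(fc)]
  if (length(unique(out)) != 2) stop2("both outcome groups must be nonempty")
  present <- intersect(genes, rownames(fc))
  if (length(present) < 2)
    stop2("need >= 2 set genes present in the fold-change matrix")
  surv <- rowMeans(fc[present, out == "survivor", drop = FALSE])
  dec <- rowMeans(fc[present, out == "deceased", drop = FALSE])
  w <- welch_t(surv, dec)
  list(t = w$t, dof = w$dof, p_value = w$p_value,
       mean_survivor = mean(surv), sd_survivor = stats::sd(surv),
       mean_deceased = mean(dec), sd_deceased = stats::sd(dec),
       gene_means = data.frame(gene_id = present, survivor = unname(surv),
                               deceased = unname(dec), stringsAsFactors = FALSE))
}
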