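# Per-patient pre/post log2 fold changes and the DEG filter
# (|log2FC| >= 1 and p < 0.05 by default).

#' Per-patient post - pre log2 fold changes
#'
#' Expression is already on the log2 scale, so the per-patient fold change
#' is a simple column difference post - pre.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param meta sample metadata bound to `expr`.
#' @param strict if TRUE, a patient missing a timepoint is an error; the
#'   default drops such patients with a warning.
#' @return genes x patients matrix of log2 fold changes.
#' @export
per_patient_log2fc <- function(expr, meta, strict = FALSE) {
  validate_expression(expr)
  validate_metadata(meta, expr)
  tab <- table(meta$patient_id, meta$timepoint)
  complete <- rownames(tab)[tab[, "pre", drop = TRUE] == 1 &
                            tab[, "post", drop = TRUE] == 1]
  incomplete <- setdiff(unique(meta$patient_id), complete)
  if (length(incomplete)) {
    msg <- paste0("patient(s) missing a timepoint: ",
                  paste(incomplete, collapse = ", "))
    if (strict) stop2(msg)
    warning(msg, call. = FALSE)
  }
  if (!length(complete)) stop2("no patient has both timepoints")
  # preserve patient order as first seen in the metadata
  complete <- unique(meta$patient_id)[unique(meta$patient_id) %in% complete]
  pre_col <- meta$sample_id[match(paste(complete, "pre"),
                                  paste(meta$patient_id, meta$timepoint))]
  post_col <- meta$sample_id[match(paste(complete, "post"),
                                   paste(meta$patient_id, meta$timepoint))]
  fc <- expr[, post_col, drop = FALSE] - expr[, pre_col, drop = FALSE]
  colnames(fc) <- complete
  fc
}

#' Exclude genes below a mean-expression floor
#'
#' Untested near-zero genes destabilise log fold changes; the floor is a
#' mean log2 expression across all samples (default 1.0).
#'
#' @param expr log2 expression matrix.
#' @param floor minimum mean log2 expression to keep a gene.
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(expr, floor = 1) {
  expr[rowMeans(expr) >= floor, , drop = FALSE]
}

#' Call differentially expressed genes from a fold-change matrix
#'
#' The group fold change is the mean of per-patient log2 fold changes; the
#' p-value is a two-sided one-sample t-test of those per-patient differences
#' against zero (the natural paired test for a pre/post design). A gene is a
#' DEG iff |group log2FC| >= `fc_threshold` and p < `p_threshold`.
#' Benjamini-Hochberg q-values are reported as an extra column but do not
#' enter the DEG call. Genes with zero variance across patients and nonzero
#' mean cannot be tested (t undefined) and are flagged, with `is_deg` FALSE.
#'
#' @param fc genes x patients log2 fold-change matrix.
#' @param patients optional subset of patient ids to use.
#' @param fc_threshold absolute log2 fold-change threshold (default 1).
#' @param p_threshold raw p-value threshold (default 0.05).
#' @return data.frame: gene_id, group_log2fc, t, p_value, q_value, is_deg,
#'   direction ("up"/"down"), zero_variance.
#' @export
call_degs <- function(fc, patients = colnames(fc),
                      fc_threshold = 1, p_threshold = 0.05) {
  miss <- setdiff(patients, colnames(fc))
  if (length(miss)) stop2("unknown patient(s): ", paste(miss, collapse = ", "))
  m <- fc[, patients, drop = FALSE]
  n <- ncol(m)
  if (n < 2)
    stop2("need >= 2 patients for a paired t-test; ",
          "use per_patient_log2fc() alone for fold-change-only screening")
  mu <- rowMeans(m)
  sdv <- row_sds(m)
  tstat <- mu / (sdv / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  zero_var <- sdv == 0
  # all-zero rows: mean 0, sd 0 -> t is 0/0; define t = 0, p = 1
  allzero <- zero_var & mu == 0
  tstat[allzero] <- 0
  p[allzero] <- 1
  p[zero_var & !allzero] <- NA_real_
  q <- stats::p.adjust(p, method = "BH")
  is_deg <- !is.na(p) & abs(mu) >= fc_threshold & p < p_threshold
  data.frame(
    gene_id = rownames(m),
    group_log2fc = unname(mu),
    t = unname(tstat),
    p_value = unname(p),
    q_value = unname(q),
    is_deg = unname(is_deg),
    direction = ifelse(mu >= 0, "up", "down"),
    zero_variance = unname(zero_var & !allzero),
    stringsAsFactors = FALSE)
}

#' Welch two-sample DEG test (sensitivity analysis)
#'
#' Alternative to the paired test: Welch's t between the pre and post sample
#' groups per gene, ignoring pairing. Offered for sensitivity analysis only.
#'
#' @inheritParams per_patient_log2fc
#' @param fc_threshold,p_threshold DEG thresholds as in [call_degs()].
#' @return data.frame like [call_degs()] (without q/zero-variance columns).
#' @export
welch_degs <- function(expr, meta, fc_threshold = 1, p_threshold = 0.05) {
  validate_expression(expr)
  validate_metadata(meta, expr)
  pre <- expr[, meta$sample_id[meta$timepoint == "pre"], drop = FALSE]
  post <- expr[, meta$sample_id[meta$timepoint == "post"], drop = FALSE]
  res <- t(vapply(seq_len(nrow(expr)), function(i) {
    w <- welch_t(post[i, ], pre[i, ])
    c(fc = mean(post[i, ]) - mean(pre[i, ]), t = w$t, p = w$p_value)
  }, numeric(3)))
  data.frame(
    gene_id = rownames(expr),
    group_log2fc = res[, "fc"],
    t = res[, "t"],
    p_value = res[, "p"],
    is_deg = abs(res[, "fc"]) >= fc_threshold & res[, "p"] < p_threshold,
    direction = ifelse(res[, "fc"] >= 0, "up", "down"),
    stringsAsFactors = FALSE)
}
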