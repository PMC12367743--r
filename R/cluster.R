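# Hierarchical clustering of per-patient fold-change profiles over the DEG
# set, and agreement of the top-level partition with outcome/arm labels.
# Clustering is delegated to stats::hclust behind this module's interface;
# merge tie-breaking follows hclust's lowest-index convention.

#' Cluster patients on DEG fold-change profiles
#'
#' Agglomerative clustering of patient columns restricted to the DEG genes.
#' Default distance is Euclidean with average linkage: the DEG filter on a
#' paired design tends to retain genes that respond coherently within a
#' patient group, a profile that is nearly constant across the retained
#' genes — there 1 - Pearson correlation is driven by noise alone, while
#' Euclidean distance keeps the group-level magnitude signal. Correlation
#' distance (the common heatmap convention) and Ward/complete linkage are
#' available by argument.
#'
#' @param fc genes x patients log2 fold-change matrix.
#' @param deg_genes nonempty subset of rownames(fc) to cluster on.
#' @param distance "euclidean" or "correlation" (1 - Pearson r).
#' @param linkage "average", "ward" (ward.D2) or "complete".
#' @return object of class `patient_dendrogram`: list with the `hclust`
#'   fit (`merge`, `height`, `labels`) and the call parameters.
#' @export
cluster_patients <- function(fc, deg_genes,
                             distance = c("euclidean", "correlation"),
                             linkage = c("average", "ward", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (ncol(fc) < 2) stop2("need >= 2 patients")
  deg_genes <- unique(deg_genes)
  miss <- setdiff(deg_genes, rownames(fc))
  if (length(miss) || !length(deg_genes))
    stop2("deg_genes must be a nonempty subset of the fold-change genes")
  m <- fc[deg_genes, , drop = FALSE]
  if (distance == "correlation") {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
      stop2("zero-variance patient column(s) under correlation distance: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(m))
  } else {
    d <- stats::dist(t(m))
  }
  hc <- stats::hclust(d, method = switch(linkage, average = "average",
                                         ward = "ward.D2",
                                         complete = "complete"))
  structure(list(hclust = hc, distance = distance, linkage = linkage,
                 n_genes = nrow(m)), class = "patient_dendrogram")
}

#' @export
print.patient_dendrogram <- function(x, ...) {
  cat("patient_dendrogram:", length(x$hclust$labels), "patients,",
      x$n_genes, "genes;", x$distance, "distance,", x$linkage, "linkage\n")
  invisible(x)
}

#' Flat k-cluster assignment from a patient dendrogram
#' @param dend a `patient_dendrogram`.
#' @param k number of clusters.
#' @return named integer vector of cluster ids per patient.
#' @export
cut_patients <- function(dend, k = 2) {
  if (k > length(dend$hclust$labels)) stop2("k exceeds the number of leaves")
  stats::cutree(dend$hclust, k = k)
}

#' Agreement of the k-cluster cut with outcome and arm labels
#'
#' Cross-tabulates the k-cluster partition against the outcome and
#' treatment-arm labels and reports the adjusted Rand index for each.
#'
#' @param dend a `patient_dendrogram`.
#' @param meta sample metadata (patient outcome/arm lookup).
#' @param k number of clusters (default 2).
#' @return list with `clusters`, `outcome_table`, `arm_table`,
#'   `ari_outcome`, `ari_arm`.
#' @export
outcome_concordance <- function(dend, meta, k = 2) {
  cl <- cut_patients(dend, k)
  pat <- unique(meta[, c("patient_id", "outcome", "arm")])
  idx <- match(names(cl), pat$patient_id)
  if (anyNA(idx)) stop2("dendrogram patient(s) absent from metadata")
  outcome <- pat$outcome[idx]
  arm <- pat$arm[idx]
  list(clusters = cl,
       outcome_table = table(cluster = cl, outcome = outcome),
       arm_table = table(cluster = cl, arm = arm),
       ari_outcome = adjusted_rand_index(cl, outcome),
       ari_arm = adjusted_rand_index(cl, arm))
}

#' Export a patient dendrogram as a Newick string
#' @param dend a `patient_dendrogram`.
#' @return single-element character vector (Newick with branch lengths).
#' @export
as_newick <- function(dend) {
  ape::write.tree(ape::as.phylo(dend$hclust))
}
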