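# Overrepresentation analysis of direction-filtered DEG lists
# (hypergeometric upper tail) and an ssGSEA-style per-sample gene-set
# variation score (rank random walk), with a pre/post-delta group comparison.

#' Extract a direction-filtered DEG gene list
#'
#' @param degs DEG table from [call_degs()].
#' @param direction "down", "up", or "both".
#' @return character vector of gene ids.
#' @export
deg_gene_list <- function(degs, direction = c("down", "up", "both")) {
  direction <- match.arg(direction)
  keep <- degs$is_deg
  if (direction != "both") keep <- keep & degs$direction == direction
  degs$gene_id[keep]
}

#' Hypergeometric overrepresentation analysis
#'
#' For each gene set, with N universe genes, K set genes in the universe,
#' n list genes and k overlap, the p-value is the upper tail
#' P(X >= k) of the hypergeometric distribution — the chance of at least k
#' set members in a random draw of n from the universe. Sets with no genes
#' in the universe are skipped. Raw p-values drive the ranking (sorted
#' ascending, ties by set name); Benjamini-Hochberg q-values are an extra
#' column.
#'
#' @param deg_genes character vector of differentially expressed gene ids
#'   (must be a subset of `universe`).
#' @param collection a `gene_set_collection`.
#' @param universe character vector of background gene ids (e.g. all genes
#'   passing the expression prefilter).
#' @return data.frame: set_name, k, K, n, N, p_value, q_value.
#' @export
overrepresentation <- function(deg_genes, collection, universe) {
  if (anyDuplicated(universe)) stop2("duplicate ids in universe")
  outside <- setdiff(deg_genes, universe)
  if (length(outside))
    stop2("DEG gene(s) outside universe: ",
          paste(utils::head(outside, 5), collapse = ", "))
  empty <- data.frame(set_name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE)
  if (!length(deg_genes)) {
    warning("empty DEG list; no enrichment computed", call. = FALSE)
    return(empty)
  }
  N <- length(universe)
  n <- length(deg_genes)
  rows <- lapply(names(collection$sets), function(nm) {
    set_u <- intersect(collection$sets[[nm]], universe)
    K <- length(set_u)
    if (K == 0) return(NULL)
    k <- length(intersect(set_u, deg_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rank random-walk enrichment statistic for one sample.
# z: named genewise z-scores; members: logical over genes; tau: weight
# exponent. Score = sum_i (P_hit(i) - P_miss(i)) over the full descending-z
# ranking (integral/ssGSEA form).
walk_score <- function(z, members, tau) {
  ord <- order(z, decreasing = TRUE)
  inset <- members[ord]
  w <- abs(z[ord])^tau
  w[!inset] <- 0
  denom_hit <- sum(w)
  if (denom_hit == 0) w[inset] <- 1  # all-zero weights: fall back to uniform
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!inset) / sum(!inset)
  sum(p_hit - p_miss)
}

#' Per-sample gene-set variation scores (ssGSEA-style)
#'
#' For each sample, genes are ranked by descending genewise z-score (after
#' batch centering). The walk accumulates set members weighted by |z|^tau
#' against non-members stepped uniformly; the score is the sum of
#' (P_hit - P_miss) over all ranks. At tau = 0 the score is rank-only
#' (invariant to monotone transforms of expression) and antisymmetric under
#' ranking reversal; its maximum over rankings is N/2, attained when the
#' set occupies the top K ranks.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param meta sample metadata (used for batch centering).
#' @param collection a `gene_set_collection`; every set must have
#'   1 <= K < N genes present.
#' @param tau weight exponent on |z| (default 0.25).
#' @return data.frame: sample_id, set_name, score.
#' @export
set_variation_scores <- function(expr, meta, collection, tau = 0.25) {
  centered <- batch_center(expr, meta)
  z <- zscore_rows(centered)
  N <- nrow(z)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- rownames(z) %in% collection$sets[[nm]]
    K <- sum(members)
    if (K == 0) stop2("set '", nm, "' has no genes in the matrix")
    if (K == N) stop2("set '", nm, "' covers every gene: walk degenerate")
    scores <- vapply(seq_len(ncol(z)), function(j)
      walk_score(z[, j], members, tau), numeric(1))
    data.frame(sample_id = colnames(z), set_name = nm, score = scores,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare per-patient set-score deltas between treatment arms
#'
#' Delta = post - pre score per patient; Welch's two-sample t-test of the
#' deltas between arms.
#'
#' @param scores output of [set_variation_scores()] (or any sample x set
#'   score table).
#' @param meta sample metadata.
#' @param set_name set to compare.
#' @return list with `t`, `dof`, `p_value`, per-arm mean deltas, and the
#'   per-patient `deltas` table.
#' @export
compare_set_scores <- function(scores, meta, set_name) {
  s <- scores[scores$set_name == set_name, , drop = FALSE]
  if (!nrow(s)) stop2("no scores for set '", set_name, "'")
  m <- merge(s, meta[, c("sample_id", "patient_id", "timepoint", "arm")],
             by = "sample_id")
  wide <- merge(m[m$timepoint == "pre", c("patient_id", "arm", "score")],
                m[m$timepoint == "post", c("patient_id", "score")],
                by = "patient_id", suffixes = c("_pre", "_post"))
  wide$delta <- wide$score_post - wide$score_pre
  arms <- sort(unique(wide$arm))
  if (length(arms) != 2) stop2("need exactly 2 arms")
  d1 <- wide$delta[wide$arm == arms[1]]
  d2 <- wide$delta[wide$arm == arms[2]]
  if (length(d1) < 2 || length(d2) < 2)
    stop2("each arm needs >= 2 patients with paired scores")
  w <- welch_t(d1, d2)
  list(t = w$t, dof = w$dof, p_value = w$p_value,
       arms = arms, mean_delta = stats::setNames(c(mean(d1), mean(d2)), arms),
       deltas = wide)
}
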