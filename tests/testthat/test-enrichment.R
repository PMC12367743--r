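# enrichment: hypergeometric overrepresentation and the rank-walk score.

make_collection <- function(...) new_gene_set_collection(list(...))

test_that("hypergeometric worked example: N=10, K=3, n=5, k=2 gives p = 0.5", {
  # enumeration over C(10,5) = 252 draws: 105 with k = 2 plus 21 with k = 3
  universe <- paste0("G", 1:10)
  col <- make_collection(S = universe[1:3])
  degs <- c(universe[1:2], universe[4:6])  # overlap 2
  res <- overrepresentation(degs, col, universe)
  expect_equal(res$p_value, 126 / 252, tolerance = 1e-12)
  expect_identical(res$k, 2L)
})

test_that("overrepresentation edge cases", {
  universe <- paste0("G", 1:10)
  col <- make_collection(S = universe[1:3])
  # zero overlap: P(X >= 0) = 1
  res0 <- overrepresentation(universe[4:5], col, universe)
  expect_equal(res0$p_value, 1)
  # saturated draw: list = universe -> k = K, p = 1
  res_all <- overrepresentation(universe, col, universe)
  expect_equal(res_all$k, 3L)
  expect_equal(res_all$p_value, 1)
  expect_warning(res_e <- overrepresentation(character(0), col, universe),
                 "empty")
  expect_identical(nrow(res_e), 0L)
  expect_error(overrepresentation("X9", col, universe), "outside universe")
  # sets with no genes in the universe are skipped
  col2 <- make_collection(S = universe[1:3], OUT = c("Z1", "Z2"))
  expect_identical(overrepresentation(universe[1:2], col2, universe)$set_name,
                   "S")
})

test_that("overrepresentation p is monotone nonincreasing in k", {
  universe <- paste0("G", 1:40)
  col <- make_collection(S = universe[1:8])
  p_at_k <- vapply(0:8, function(k) {
    degs <- c(universe[seq_len(k)], universe[9:(9 + 10 - k - 1)])
    overrepresentation(degs, col, universe)$p_value
  }, numeric(1))
  expect_true(all(diff(p_at_k) <= 1e-12))
})

test_that("walk score attains the tau = 0 closed-form extremes", {
  # set at the top K ranks: score = N/2; at the bottom: -N/2
  for (N in c(8, 20)) {
    for (K in c(2, 4)) {
      genes <- paste0("G", 1:N)
      z <- seq(N, 1)  # descending: G1 highest
      names(z) <- genes
      top <- mda5tx:::walk_score(z, genes %in% genes[1:K], tau = 0)
      bottom <- mda5tx:::walk_score(z, genes %in% genes[(N - K + 1):N], tau = 0)
      expect_equal(top, N / 2, tolerance = 1e-12)
      expect_equal(bottom, -N / 2, tolerance = 1e-12)
    }
  }
  # uniform interleaving with K = N/2: near-zero relative to the max N/2
  z <- seq(12, 1); names(z) <- paste0("G", 1:12)
  inter <- mda5tx:::walk_score(z, seq_along(z) %% 2 == 1, tau = 0)
  expect_lte(abs(inter) / 6, 0.2)
})

test_that("tau = 0 walk is rank-only and antisymmetric under reversal", {
  set.seed(21)
  for (i in 1:20) {
    N <- sample(6:15, 1)
    z <- rnorm(N); names(z) <- paste0("G", 1:N)
    members <- seq_len(N) %in% sample(N, sample(2:(N - 2), 1))
    s <- mda5tx:::walk_score(z, members, tau = 0)
    # monotone transform leaves the ranking, hence the score, unchanged
    expect_equal(mda5tx:::walk_score(exp(z) + 3, members, tau = 0), s,
                 tolerance = 1e-12)
    # reversing the ranking negates the score
    expect_equal(mda5tx:::walk_score(-z, members, tau = 0), -s,
                 tolerance = 1e-12)
  }
})

test_that("set_variation_scores validates set coverage", {
  co <- generate_cohort(tiny_design(seed = 4, noise_sd = 0.5, effect = -2))
  all_genes <- rownames(co$expression)
  expect_error(
    set_variation_scores(co$expression, co$metadata,
                         make_collection(ALL = all_genes)),
    "degenerate")
  scores <- set_variation_scores(co$expression, co$metadata, co$gene_sets,
                                 tau = 0.25)
  expect_identical(nrow(scores), ncol(co$expression))
  # survivor post samples were suppressed on the module -> lower walk score
  m <- merge(scores, co$metadata, by = "sample_id")
  surv_post <- m$score[m$outcome == "survivor" & m$timepoint == "post"]
  surv_pre <- m$score[m$outcome == "survivor" & m$timepoint == "pre"]
  expect_lt(mean(surv_post), mean(surv_pre))
})

test_that("compare_set_scores: symmetry and degenerate contracts", {
  scores <- data.frame(
    sample_id = c(paste0("P", 1:4, "_pre"), paste0("P", 1:4, "_post")),
    set_name = "S",
    score = c(1, 2, 3, 4, 2, 3, 4, 5))  # identical delta = 1 everywhere
  meta <- toy_meta(paste0("P", 1:4), arms = c("BRT", "BRT", "TC", "TC"))
  res <- compare_set_scores(scores, meta, "S")
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  # swapping arm labels negates t, preserves p
  scores2 <- scores; scores2$score[5:8] <- c(0, 1, 9, 9.5)
  meta_sw <- meta
  meta_sw$arm <- ifelse(meta$arm == "BRT", "TC", "BRT")
  r1 <- compare_set_scores(scores2, meta, "S")
  r2 <- compare_set_scores(scores2, meta_sw, "S")
  expect_equal(r2$t, -r1$t, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
  expect_error(compare_set_scores(scores, meta[meta$patient_id != "P1", ], "S"),
               ">= 2 patients")
})

test_that("planted arm-specific suppression is detected at stated seeds", {
  # a cohort whose arm labels align with outcome, so the survivor-only
  # module suppression is arm-specific by construction; 3 patients per arm
  aligned_design <- function(seed) {
    patients <- data.frame(
      patient_id = paste0("P", 1:6),
      arm = rep(c("BRT", "TC"), each = 3),
      outcome = rep(c("survivor", "deceased"), each = 3),
      batch = "b1", stringsAsFactors = FALSE)
    cohort_design(patients, n_genes = 100L, modules = list(mod = 20L),
                  effect_sizes = list(mod = c(survivor = -3, deceased = 0)),
                  batch_offsets = c(b1 = 0), noise_sd = 0.5, seed = seed)
  }
  for (seed in c(101, 202, 303)) {
    co <- generate_cohort(aligned_design(seed))
    scores <- set_variation_scores(co$expression, co$metadata, co$gene_sets)
    res <- compare_set_scores(scores, co$metadata, "mod")
    expect_lt(res$p_value, 0.05)
  }
})
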