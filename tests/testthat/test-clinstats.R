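# clinical_stats: first-principles tests vs published values and oracles.

test_that("Fisher's exact reproduces the published 2x2 p-values", {
  # anti-SS-A/Ro-52: 2/6 vs 0/7 -> 0.192
  expect_equal(round(fisher_exact_2x2(matrix(c(2, 0, 4, 7), 2))$p_value, 3),
               0.192)
  # heliotrope rash: 4/7 vs 2/7 -> 0.592
  expect_equal(round(fisher_exact_2x2(matrix(c(4, 2, 3, 5), 2))$p_value, 3),
               0.592)
  # identical rows -> 1
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 0, 1, 1), 2)), "integer")
})

test_that("Fisher matches the base-R oracle on random tables", {
  set.seed(14)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square: degenerate tables and oracle agreement", {
  expect_equal(chi_square_test(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square_test(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "fisher")
  set.seed(15)
  for (i in 1:30) {
    tab <- matrix(rpois(6, 8) + 1, 2)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    mine <- chi_square_test(tab)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_identical(mine$dof, unname(ref$parameter[[1]]))
  }
})

test_that("Mann-Whitney exact worked examples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)  # 2 of 6 rank splits
  expect_identical(r$method, "exact")
  # identical multisets: U at its null centre, p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # positive rescaling leaves ranks, hence (U, p), unchanged
  a <- mann_whitney_u(c(5, 9, 2), c(7, 1, 8))
  b <- mann_whitney_u(c(5, 9, 2) * 10, c(7, 1, 8) * 10)
  expect_equal(a$U, b$U); expect_equal(a$p_value, b$p_value)
})

test_that("Mann-Whitney agrees with wilcox.test on both branches", {
  set.seed(16)
  for (i in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)  # continuous: no ties
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    mine <- mann_whitney_u(x, y)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
  x <- rnorm(10); y <- rnorm(9)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  mine <- mann_whitney_u(x, y)
  expect_identical(mine$method, "normal")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Welch t: conventions, equivariance, oracle agreement", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0); expect_equal(r$p_value, 1)
  # both variances zero
  expect_equal(welch_t(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(welch_t(c(2, 2), c(3, 3)), "undefined")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
  set.seed(17)
  x <- rnorm(6); y <- rnorm(9, 1)
  shift <- welch_t(x + 5, y + 5)
  base <- welch_t(x, y)
  expect_equal(shift$t, base$t, tolerance = 1e-9)
  expect_equal(shift$p_value, base$p_value, tolerance = 1e-9)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = 2)
    ref <- stats::t.test(x, y)
    mine <- welch_t(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$dof, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("log-rank: symmetry, null, and survival-package oracle", {
  same <- data.frame(time_months = c(1, 2, 3, 1, 2, 3),
                     event = c(1, 0, 1, 1, 0, 1),
                     group = rep(c("a", "b"), each = 3))
  r <- logrank_two_group(same)
  expect_equal(r$statistic, 0); expect_equal(r$p_value, 1)

  set.seed(18)
  for (i in 1:20) {
    n <- sample(6:14, 1)
    rec <- data.frame(
      time_months = round(rexp(n, 0.2) + 0.5, 1),
      event = rbinom(n, 1, 0.8),
      group = sample(rep(c("a", "b"), length.out = n)))
    if (sum(rec$event) == 0) next
    mine <- logrank_two_group(rec)
    ref <- survival::survdiff(
      survival::Surv(time_months, event) ~ group, data = rec)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
    expect_equal(mine$p_value,
                 stats::pchisq(ref$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
    swap <- rec; swap$group <- ifelse(rec$group == "a", "b", "a")
    expect_equal(logrank_two_group(swap)$statistic, mine$statistic,
                 tolerance = 1e-12)
  }
  expect_error(logrank_two_group(same[same$group == "a", ]), "2 groups")
})

test_that("KM export is a nonincreasing step function per group", {
  set.seed(19)
  rec <- data.frame(time_months = rexp(20, 0.2) + 0.1,
                    event = rbinom(20, 1, 0.7),
                    group = rep(c("a", "b"), 10))
  km <- km_curve(rec)
  for (g in c("a", "b")) {
    s <- km$survival[km$group == g]
    expect_true(all(diff(s) <= 0))
    expect_equal(s[1], 1)
  }
})

test_that("clinical report chooses tests per variable type", {
  clinical <- data.frame(
    patient_id = paste0("P", 1:13),
    arm = c(rep("TC", 6), rep("BRT", 7)),
    age = c(61, 70, 66, 59, 68, 64, 45, 39, 60, 52, 41, 48, 55),
    ssa_positive = c(1, 1, 0, 0, 0, 0, rep(0, 7)),
    gottron = rep(1, 13),
    stringsAsFactors = FALSE)
  rep <- clinical_report(clinical, group = "arm")
  expect_identical(rep$test[rep$variable == "age"], "mann_whitney")
  ssa <- rep[rep$variable == "ssa_positive", ]
  expect_identical(ssa$test, "fisher_exact")
  # 2/6 vs 0/7 must reproduce the direct Fisher computation
  expect_equal(ssa$p_value,
               fisher_exact_2x2(matrix(c(2, 0, 4, 7), 2))$p_value,
               tolerance = 1e-12)
  gott <- rep[rep$variable == "gottron", ]
  expect_identical(gott$note, "single observed level")
  expect_true(is.na(gott$p_value))

  sv <- data.frame(patient_id = clinical$patient_id,
                   time_months = c(2.5, 12, 2.2, 12, 12, 12, rep(12, 7)),
                   event = c(1, 0, 1, 0, 0, 0, rep(0, 7)))
  rep2 <- clinical_report(clinical, sv, group = "arm")
  expect_true("prognosis_12mo" %in% rep2$variable)
  lr <- rep2$p_value[rep2$variable == "prognosis_12mo"]
  expect_true(lr > 0 && lr < 1)

  # identical groups: every computable p is 1
  same <- data.frame(patient_id = paste0("Q", 1:8),
                     arm = rep(c("TC", "BRT"), each = 4),
                     flag = rep(c(0, 1), 4))
  rep3 <- clinical_report(same, group = "arm")
  expect_equal(rep3$p_value[rep3$variable == "flag"], 1)
})
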