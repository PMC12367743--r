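# Clinical statistics toolkit, implemented from first principles:
# two-sided Fisher's exact test (point-probability rule), Pearson chi-square,
# Mann-Whitney U (exact by enumeration at small n), Welch's t, and the
# two-group log-rank test, plus a baseline-characteristics report builder.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the table count follows a hypergeometric
#' distribution. The two-sided p is the sum of point probabilities of all
#' tables no more probable than the observed one (the point-probability
#' rule, the convention used by standard statistical software). Computed in
#' log space for stability.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list with `p_value` and the observed table's point probability.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 4, 7), 2))$p_value # 0.192
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2))
    stop2("fisher_exact_2x2 needs a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop2("counts must be nonnegative integers")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); n <- sum(table)
  if (n == 0) stop2("empty table")
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  a <- lo:hi
  logp <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  obs <- table[1, 1]
  # same relative tolerance convention as standard implementations
  keep <- logp <= logp[a == obs] + log(1 + 1e-7)
  list(p_value = min(1, sum(exp(logp[keep]))),
       point_probability = exp(logp[a == obs]))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction. Zero expected cells are an error (use Fisher's
#' exact test instead).
#'
#' @param table r x c matrix of nonnegative counts.
#' @return list with `statistic`, `dof`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  if (!is.matrix(table) || any(table < 0)) stop2("need a nonnegative count matrix")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected == 0))
    stop2("zero expected cell; use fisher_exact_2x2 for sparse tables")
  stat <- sum((table - expected)^2 / expected)
  dof <- as.integer((nrow(table) - 1) * (ncol(table) - 1))
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       expected = expected)
}

#' Mann-Whitney U test
#'
#' U counts, over all cross-pairs, the times an x precedes a y (ties count
#' one half). For n_x + n_y <= `exact_limit` the two-sided p is exact: every
#' assignment of the pooled (mid)ranks to the x positions is enumerated and
#' p = min(1, 2 * min(P(U <= u), P(U >= u))). Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_limit switch to the approximation above this pooled size.
#' @return list with `U`, `p_value`, `method` ("exact"/"normal").
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y)) stop2("both samples must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n <= exact_limit) {
    splits <- utils::combn(n, nx)
    u_all <- colSums(matrix(r[splits], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p_le <- mean(u_all <= u_obs + eps)
    p_ge <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal"
  }
  list(U = u_obs, p_value = p, method = method)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided.
#' When both variances are zero: equal means give p = 1 by convention,
#' different means are an error (no variance estimate exists).
#'
#' @param x,y numeric samples with >= 2 observations each.
#' @return list with `t`, `dof`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop2("need >= 2 observations per sample")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mx == my)
      return(list(t = 0, dof = nx + ny - 2, p_value = 1, mean_x = mx, mean_y = my))
    stop2("both variances zero with different means: t undefined")
  }
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  dof <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, dof = dof, p_value = 2 * stats::pt(-abs(t), dof),
       mean_x = mx, mean_y = my)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group 1 are compared
#' with their hypergeometric expectation given the risk sets; the statistic
#' is (sum O - sum E)^2 / sum V, referred to chi-square with 1 dof.
#' Simultaneous events use the standard tie-corrected variance.
#'
#' @param records data.frame with columns `time_months` (> 0), `event`
#'   (1 = death, 0 = censored) and `group` (exactly two levels).
#' @return list with `statistic`, `p_value`, `observed`, `expected` (per
#'   group, in level order).
#' @export
logrank_two_group <- function(records) {
  need <- c("time_months", "event", "group")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop2("records missing column(s): ", paste(miss, collapse = ", "))
  groups <- sort(unique(records$group))
  if (length(groups) != 2) stop2("need exactly 2 groups")
  if (!any(records$event == 1)) stop2("need >= 1 event")
  g1 <- records$group == groups[1]
  event_times <- sort(unique(records$time_months[records$event == 1]))
  O1 <- E1 <- V <- 0
  for (t in event_times) {
    at_risk <- records$time_months >= t
    n_t <- sum(at_risk); n1 <- sum(at_risk & g1)
    d_t <- sum(records$time_months == t & records$event == 1)
    d1 <- sum(records$time_months == t & records$event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  if (V == 0)
    return(list(statistic = 0, p_value = 1,
                observed = c(O1, sum(records$event) - O1),
                expected = c(E1, sum(records$event) - E1)))
  stat <- (O1 - E1)^2 / V
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = c(O1, sum(records$event) - O1),
       expected = c(E1, sum(records$event) - E1))
}

#' Kaplan-Meier step function (plotting convenience)
#'
#' @param records survival records as in [logrank_two_group()]; `group`
#'   optional.
#' @return data.frame with group, time, survival (nonincreasing per group).
#' @export
km_curve <- function(records) {
  if (is.null(records$group)) records$group <- "all"
  out <- lapply(split(records, records$group), function(r) {
    times <- sort(unique(r$time_months[r$event == 1]))
    s <- 1
    surv <- vapply(times, function(t) {
      n_t <- sum(r$time_months >= t)
      d_t <- sum(r$time_months == t & r$event == 1)
      s <<- s * (1 - d_t / n_t)
      s
    }, numeric(1))
    data.frame(group = r$group[1], time = c(0, times), survival = c(1, surv))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Baseline-characteristics comparison report
#'
#' One row per clinical variable, compared between the two levels of
#' `group`: continuous variables get mean +/- sd per group with a
#' Mann-Whitney p (Welch p as an extra column); categorical variables get
#' counts/percent with Fisher's exact p for 2x2 or chi-square for larger
#' tables; a survival table adds a log-rank row. Per-variable missing values
#' (NA) are dropped for that row, so denominators may differ across rows.
#' Variables with a single observed level get no p-value, with a note.
#'
#' @param clinical data.frame, one row per patient; `group` column plus
#'   variables to compare.
#' @param survival optional survival records (see [logrank_two_group()]).
#' @param group name of the grouping column (two levels).
#' @param variables variables to report; default all except patient_id and
#'   the grouping column.
#' @return data.frame: variable, summaries per group, test, p_value, note.
#' @export
clinical_report <- function(clinical, survival = NULL, group = "arm",
                            variables = NULL) {
  if (!group %in% names(clinical)) stop2("grouping column '", group, "' absent")
  levels <- sort(unique(clinical[[group]]))
  if (length(levels) != 2) stop2("grouping column must have exactly 2 levels")
  if (is.null(variables))
    variables <- setdiff(names(clinical), c("patient_id", group))
  g <- clinical[[group]]
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    ok <- !is.na(x)
    xv <- x[ok]; gv <- g[ok]
    x1 <- xv[gv == levels[1]]; x2 <- xv[gv == levels[2]]
    continuous <- is.numeric(xv) && length(unique(xv)) > 2
    if (continuous) {
      fmt <- function(z) sprintf("%.1f ± %.1f", mean(z), stats::sd(z))
      p <- tryCatch(mann_whitney_u(x1, x2)$p_value, error = function(e) NA_real_)
      pw <- tryCatch(welch_t(x1, x2)$p_value, error = function(e) NA_real_)
      data.frame(variable = v, group1 = fmt(x1), group2 = fmt(x2),
                 test = "mann_whitney", p_value = p, p_welch = pw,
                 note = "", stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(gv, levels = levels), xv)
      fmt <- function(z) paste(sprintf("%s: %d", colnames(tab),
                                       as.integer(z)), collapse = ", ")
      if (ncol(tab) < 2) {
        return(data.frame(variable = v, group1 = fmt(tab[1, ]),
                          group2 = fmt(tab[2, ]), test = "none",
                          p_value = NA_real_, p_welch = NA_real_,
                          note = "single observed level",
                          stringsAsFactors = FALSE))
      }
      if (ncol(tab) == 2) {
        p <- fisher_exact_2x2(as.matrix(unclass(tab)))$p_value
        test <- "fisher_exact"
      } else {
        p <- tryCatch(chi_square_test(as.matrix(unclass(tab)))$p_value,
                      error = function(e) NA_real_)
        test <- "chi_square"
      }
      data.frame(variable = v, group1 = fmt(tab[1, ]), group2 = fmt(tab[2, ]),
                 test = test, p_value = p, p_welch = NA_real_, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(survival)) {
    sv <- survival
    if (is.null(sv$group)) {
      sv$group <- clinical[[group]][match(sv$patient_id, clinical$patient_id)]
    }
    lr <- logrank_two_group(sv)
    events <- vapply(levels, function(l)
      sum(sv$event[sv$group == l]), numeric(1))
    out <- rbind(out, data.frame(
      variable = "prognosis_12mo", group1 = sprintf("events: %d", events[1]),
      group2 = sprintf("events: %d", events[2]), test = "logrank",
      p_value = lr$p_value, p_welch = NA_real_, note = "",
      stringsAsFactors = FALSE))
  }
  out
}
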