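# Nonparametric comparison statistics used throughout the analyses:
# Mann-Whitney U (exact or tie-corrected asymptotic), Kruskal-Wallis with
# an exact permutation option at small n, Dunn's post hoc comparisons
# versus a control, Fisher's exact test, and t-based confidence intervals.

stat_row <- function(method, statistic, p_value, n_per_group, adjusted = FALSE) {
  tibble::tibble(
    method = method,
    statistic = statistic,
    p_value = p_value,
    n_per_group = list(n_per_group),
    adjusted = adjusted
  )
}

rank_tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact mode uses the null permutation distribution of U: via the exact
#' tie-free distribution when there are no ties, or full enumeration of all
#' group labelings when there are (feasible for n_x + n_y <= 16). The
#' two-sided exact p is twice the smaller tail probability, capped at 1.
#' Asymptotic mode uses the normal approximation with tie correction and a
#' continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"` (exact when feasible), `"exact"` or `"asymptotic"`.
#' @return A one-row tibble: `method`, `statistic` (U for `x`), `p_value`,
#'   `n_per_group`, `adjusted`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (mode == "auto") {
    mode <- if ((!has_ties && n <= 50) || (has_ties && n <= 14)) "exact" else "asymptotic"
  }

  if (mode == "exact") {
    if (!has_ties) {
      lo <- stats::pwilcox(u, nx, ny)
      hi <- 1 - stats::pwilcox(u - 1, nx, ny)
      p <- min(1, 2 * min(lo, hi))
    } else {
      if (n > 16) stop("exact mode with ties is limited to n_x + n_y <= 16")
      combs <- utils::combn(n, nx)
      us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
      eps <- 1e-9
      p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    }
    return(stat_row("mann_whitney_u_exact", u, p, c(nx, ny)))
  }

  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * ((n + 1) - rank_tie_term(r) / (n * (n - 1)))
  if (sigma2 <= 0) return(stat_row("mann_whitney_u_asymptotic", u, 1, c(nx, ny)))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
  stat_row("mann_whitney_u_asymptotic", u,
           min(1, 2 * stats::pnorm(-max(z, 0))), c(nx, ny))
}

kw_h <- function(r, grp_sizes, tie_denom, n) {
  ends <- cumsum(grp_sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  rsum2 <- vapply(seq_along(grp_sizes), function(i) {
    sum(r[starts[i]:ends[i]])^2 / grp_sizes[i]
  }, numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rsum2) - 3 * (n + 1)
  h / tie_denom
}

# All assignments of n items into ordered groups of the given sizes,
# as a list of index vectors (concatenated group memberships).
enumerate_assignments <- function(idx, sizes) {
  if (length(sizes) == 1L) return(list(idx))
  first <- utils::combn(idx, sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- enumerate_assignments(setdiff(idx, f), sizes[-1])
    out <- c(out, lapply(rest, function(rr) c(f, rr)))
  }
  out
}

#' Kruskal-Wallis rank test
#'
#' H statistic on ranks with tie correction; p from the chi-square reference
#' with k - 1 degrees of freedom (via [stats::kruskal.test()]), or an exact
#' permutation p obtained by full enumeration of group labelings
#' (`mode = "exact"`, feasible for total n <= 10).
#'
#' @param groups List of 2 or more non-empty numeric vectors.
#' @param mode `"chisq"` or `"exact"`.
#' @return A one-row tibble as in [mann_whitney_u()].
#' @export
kruskal_wallis <- function(groups, mode = c("chisq", "exact")) {
  mode <- match.arg(mode)
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need >= 2 non-empty groups")
  }
  sizes <- lengths(groups)
  n <- sum(sizes)
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)
  tie_denom <- 1 - rank_tie_term(r) / (n^3 - n)
  if (tie_denom <= 0) {
    # all observations identical
    return(stat_row("kruskal_wallis", 0, 1, sizes))
  }
  h <- kw_h(r, sizes, tie_denom, n)
  if (mode == "chisq") {
    kt <- stats::kruskal.test(groups)
    return(stat_row("kruskal_wallis", unname(kt$statistic),
                    unname(kt$p.value), sizes))
  }
  if (n > 12) stop("exact permutation mode is limited to total n <= 12")
  perms <- enumerate_assignments(seq_len(n), sizes)
  hs <- vapply(perms, function(ix) kw_h(r[ix], sizes, tie_denom, n), numeric(1))
  stat_row("kruskal_wallis_exact", h, mean(hs >= h - 1e-9), sizes)
}

#' Dunn's post hoc comparisons versus a control group
#'
#' Pairwise z statistics on mean ranks (pooled ranking, tie-corrected
#' variance), each experimental group compared to the control, with
#' p-values adjusted over the comparison family (Bonferroni by default).
#'
#' @param groups Named or unnamed list of numeric vectors.
#' @param control Index of the control group.
#' @param adjust Adjustment method (`"bonferroni"`, `"holm"`, `"none"`).
#' @return A tibble with one row per comparison: `comparison`, `statistic`
#'   (z), `p_raw`, `p_value` (adjusted), `n_per_group`, `adjusted`.
#' @export
dunn_posthoc <- function(groups, control = 1,
                         adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (control < 1 || control > k) stop("control index out of range")
  sizes <- lengths(groups)
  n <- sum(sizes)
  r <- rank(unlist(groups, use.names = FALSE))
  grp <- rep(seq_len(k), sizes)
  mean_ranks <- tapply(r, grp, mean)
  var_term <- n * (n + 1) / 12 - rank_tie_term(r) / (12 * (n - 1))
  nms <- names(groups) %||% paste0("group", seq_len(k))
  others <- setdiff(seq_len(k), control)
  z <- vapply(others, function(i) {
    se <- sqrt(var_term * (1 / sizes[control] + 1 / sizes[i]))
    if (se == 0) return(0)
    (mean_ranks[[i]] - mean_ranks[[control]]) / se
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  tibble::tibble(
    method = "dunn_posthoc",
    comparison = paste(nms[others], "vs", nms[control]),
    statistic = z,
    p_raw = p_raw,
    p_value = p_adj,
    n_per_group = purrr::map(others, ~ c(sizes[control], sizes[.x])),
    adjusted = TRUE
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability method: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one, as computed by [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A one-row tibble; `statistic` is the conditional odds-ratio
#'   estimate.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be non-negative integers")
  }
  ft <- stats::fisher.test(table)
  stat_row("fisher_exact", unname(ft$estimate), ft$p.value,
           c(sum(table[1, ]), sum(table[2, ])))
}

#' Mean with a 95% confidence interval
#'
#' t-distribution based CI on the mean (as drawn as error bars on the
#' per-cell fluorescence scatter plots); a nonparametric bootstrap is
#' available as an option for skewed samples.
#'
#' @param values Numeric vector, n >= 2.
#' @param method `"t"` or `"bootstrap"`.
#' @param conf Confidence level.
#' @param n_boot Bootstrap replicates (bootstrap method only).
#' @param seed Seed for the bootstrap resampling.
#' @return A one-row tibble: `mean`, `lower`, `upper`, `n`.
#' @export
mean_ci95 <- function(values, method = c("t", "bootstrap"), conf = 0.95,
                      n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need n >= 2")
  m <- mean(values)
  if (stats::sd(values) == 0) {
    return(tibble::tibble(mean = m, lower = m, upper = m, n = length(values)))
  }
  if (method == "t") {
    ci <- stats::t.test(values, conf.level = conf)$conf.int
    return(tibble::tibble(mean = m, lower = ci[1], upper = ci[2],
                          n = length(values)))
  }
  boots <- withr::with_seed(as.integer(split_seed(seed, "boot")), {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(values, replace = TRUE))
    }, numeric(1))
  })
  q <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2))
  tibble::tibble(mean = m, lower = unname(q[1]), upper = unname(q[2]),
                 n = length(values))
}
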