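#' Group summary (mean, SD, n)
#'
#' The unit of input for the summary-statistics tests: exactly what a
#' published table cell reports.
#'
#' @param label group label.
#' @param mean group mean.
#' @param sd standard deviation (>= 0).
#' @param n sample size (>= 2 for any test).
#' @return one-row data.frame of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (sd < 0) stopf("SD must be non-negative")
  if (n < 2) stopf("n must be at least 2")
  structure(data.frame(label = label, mean = mean, sd = sd, n = as.integer(n)),
            class = c("group_summary", "data.frame"))
}

#' @rdname group_summary
#' @param x raw values.
#' @export
summarize_group <- function(x, label = "group") {
  group_summary(label, mean(x), sd(x), length(x))
}

test_result <- function(statistic, df, p, method, comparison) {
  structure(data.frame(statistic = statistic, df = df, p = p, method = method,
                       comparison = comparison, row.names = NULL),
            class = c("test_result", "data.frame"))
}

check_two <- function(a, b) {
  if (a$n < 2 || b$n < 2) stopf("n must be at least 2 in both groups")
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean) return(TRUE)   # t = 0, p = 1 handled by caller
    stopf("both SDs zero with unequal means: statistic is infinite")
  }
  FALSE
}

#' Welch's two-sample t-test from summary statistics
#'
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch--Satterthwaite degrees of freedom and a two-tailed p-value; the
#' fractional-df tail comes from the t distribution (regularised incomplete
#' beta), not a table.
#'
#' @param a,b [group_summary()] rows (or any list with mean, sd, n, label).
#' @return a `test_result` (statistic, df, p, method, comparison).
#' @examples
#' welch_t_from_summary(group_summary("MA", 53.01, 4.78, 10),
#'                      group_summary("O", 44.04, 8.18, 18))  # p ~ 0.0011
#' @export
welch_t_from_summary <- function(a, b) {
  if (check_two(a, b))
    return(test_result(0, a$n + b$n - 2, 1, "welch_t",
                       paste(a$label, "vs", b$label)))
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  test_result(t, df, 2 * pt(-abs(t), df), "welch_t",
              paste(a$label, "vs", b$label))
}

#' Pooled-variance (classical) two-sample t-test from summary statistics
#'
#' Equal-variance form with `df = n_a + n_b - 2`; agrees with Welch exactly
#' when SDs and group sizes are equal.
#'
#' @inheritParams welch_t_from_summary
#' @return a `test_result`.
#' @export
pooled_t_from_summary <- function(a, b) {
  if (check_two(a, b))
    return(test_result(0, a$n + b$n - 2, 1, "pooled_t",
                       paste(a$label, "vs", b$label)))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  test_result(t, df, 2 * pt(-abs(t), df), "pooled_t",
              paste(a$label, "vs", b$label))
}

#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' U counts pairs where an x-value exceeds a y-value (ties count one half).
#' `mode = "exact"` uses the exact null distribution (no ties only);
#' `"normal"` uses the large-sample normal approximation with tie correction
#' and continuity correction; `"auto"` picks exact when there are no ties
#' and `min(n) <= 8`.
#'
#' @param x,y raw values (no missing values).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return a `test_result` (statistic = U).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stopf("empty group")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "auto") mode <- if (!ties && min(nx, ny) <= 8) "exact" else "normal"
  if (mode == "exact") {
    if (ties) stopf("exact mode is not defined with ties; use mode = 'normal'")
    # two-tailed: twice the smaller tail of the exact U distribution
    p <- 2 * min(pwilcox(U, nx, ny), 1 - pwilcox(U - 1, nx, ny))
    p <- min(1, p)
    method <- "mann_whitney_exact"
  } else {
    mu <- nx * ny / 2
    ntot <- nx + ny
    tie_tab <- table(c(x, y))
    tie_corr <- sum(tie_tab^3 - tie_tab) / (ntot * (ntot - 1))
    sigma2 <- nx * ny / 12 * ((ntot + 1) - tie_corr)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "mann_whitney_normal"
  }
  test_result(U, NA_real_, p, method, "x vs y")
}

prepare_groups <- function(groups) {
  if (is.data.frame(groups)) {
    need <- c("label", "mean", "sd", "n")
    if (!all(need %in% names(groups))) stopf("summary data.frame needs columns: %s",
                                             paste(need, collapse = ", "))
    return(groups)
  }
  if (is.list(groups)) {
    labels <- names(groups) %||% paste0("g", seq_along(groups))
    return(do.call(rbind, Map(function(x, l) summarize_group(x, l), groups, labels)))
  }
  stopf("groups must be a summary data.frame or a named list of raw vectors")
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Works from group summaries (mean, SD, n) or raw data. The pooled MSE and
#' per-comparison t statistics follow the classical one-way layout; each
#' two-sided adjusted p-value is
#' `1 - P(max_j |T_j| <= |t_i|)` under the joint multivariate-t null with
#' the Dunnett correlation structure
#' `rho_ij = sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))`, evaluated by
#' numerical integration (`mvtnorm::pmvt`); `method = "mc"` cross-checks by
#' Monte Carlo simulation of the same joint distribution.
#'
#' @param groups data.frame with columns label, mean, sd, n -- or a named
#'   list of raw numeric vectors.
#' @param control label of the control group.
#' @param method `"integration"` (default) or `"mc"`.
#' @param nsim Monte-Carlo draws for `method = "mc"`.
#' @param seed optional seed for `method = "mc"`.
#' @return data.frame: comparison, estimate, statistic, df, p_unadjusted,
#'   p_adjusted, plus attributes `anova_F`, `anova_p`, `mse`.
#' @export
anova_dunnett <- function(groups, control, method = c("integration", "mc"),
                          nsim = 1e5, seed = NULL) {
  method <- match.arg(method)
  gs <- prepare_groups(groups)
  if (!control %in% gs$label) stopf("control group '%s' not found", control)
  if (nrow(gs) < 2L) stopf("need at least one comparison group")
  i0 <- which(gs$label == control)
  others <- setdiff(seq_len(nrow(gs)), i0)
  k <- length(others)
  N <- sum(gs$n)
  df <- N - nrow(gs)
  mse <- sum((gs$n - 1) * gs$sd^2) / df
  grand <- sum(gs$n * gs$mean) / N
  ss_between <- sum(gs$n * (gs$mean - grand)^2)
  Fstat <- (ss_between / (nrow(gs) - 1)) / mse
  est <- gs$mean[others] - gs$mean[i0]
  se <- sqrt(mse * (1 / gs$n[others] + 1 / gs$n[i0]))
  tstat <- est / se
  lam <- sqrt(gs$n[others] / (gs$n[others] + gs$n[i0]))
  R <- outer(lam, lam)
  diag(R) <- 1
  p_unadj <- 2 * pt(-abs(tstat), df)
  p_adj <- numeric(k)
  if (method == "integration") {
    for (i in seq_len(k)) {
      q <- abs(tstat[i])
      p_adj[i] <- 1 - mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                                    df = as.integer(round(df)), corr = R,
                                    algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                                   maxpts = 250000))
    }
  } else {
    draws <- with_seed(seed, {
      z <- abs(mvtnorm::rmvnorm(nsim, sigma = R) / sqrt(rchisq(nsim, df) / df))
      mx <- z[, 1L]
      for (j in seq_len(ncol(z))[-1L]) mx <- pmax(mx, z[, j])
      mx
    })
    for (i in seq_len(k)) p_adj[i] <- mean(draws >= abs(tstat[i]))
  }
  p_adj <- pmin(1, pmax(p_adj, p_unadj))   # adjusted never below unadjusted
  out <- data.frame(comparison = paste(gs$label[others], "vs", control),
                    estimate = est, statistic = tstat, df = df,
                    p_unadjusted = p_unadj, p_adjusted = p_adj)
  attr(out, "anova_F") <- Fstat
  attr(out, "anova_p") <- pf(Fstat, nrow(gs) - 1, df, lower.tail = FALSE)
  attr(out, "mse") <- mse
  out
}

#' One-way ANOVA with Tukey(-Kramer) all-pairs comparisons
#'
#' Adjusted p-values from the studentized-range distribution
#' (`stats::ptukey`, itself numerical integration), with the Kramer
#' unequal-n standard error; `method = "mc"` cross-checks by simulating the
#' null max-range statistic.
#'
#' @inheritParams anova_dunnett
#' @return data.frame of all pairwise comparisons with adjusted p-values;
#'   same attributes as [anova_dunnett()].
#' @export
anova_tukey <- function(groups, method = c("integration", "mc"),
                        nsim = 1e5, seed = NULL) {
  method <- match.arg(method)
  gs <- prepare_groups(groups)
  kg <- nrow(gs)
  if (kg < 2L) stopf("need at least two groups")
  N <- sum(gs$n)
  df <- N - kg
  mse <- sum((gs$n - 1) * gs$sd^2) / df
  grand <- sum(gs$n * gs$mean) / N
  Fstat <- (sum(gs$n * (gs$mean - grand)^2) / (kg - 1)) / mse
  pairs <- utils::combn(kg, 2)
  est <- gs$mean[pairs[2, ]] - gs$mean[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / gs$n[pairs[1, ]] + 1 / gs$n[pairs[2, ]]))
  q <- abs(est) / se          # studentized range scale
  if (method == "integration") {
    p_adj <- ptukey(q, nmeans = kg, df = df, lower.tail = FALSE)
  } else {
    draws <- with_seed(seed, {
      # balanced-null max studentized range with kg groups
      z <- matrix(rnorm(nsim * kg), nsim, kg)
      mx <- z[, 1L]; mn <- z[, 1L]
      for (j in seq_len(kg)[-1L]) { mx <- pmax(mx, z[, j]); mn <- pmin(mn, z[, j]) }
      (mx - mn) / sqrt(rchisq(nsim, df) / df)
    })
    p_adj <- vapply(q, function(qi) mean(draws >= qi), numeric(1))
  }
  tstat <- est / (se * sqrt(2))
  p_unadj <- 2 * pt(-abs(tstat), df)
  out <- data.frame(comparison = paste(gs$label[pairs[2, ]], "vs",
                                       gs$label[pairs[1, ]]),
                    estimate = est, statistic = tstat, df = df,
                    p_unadjusted = p_unadj, p_adjusted = pmax(p_adj, p_unadj))
  attr(out, "anova_F") <- Fstat
  attr(out, "anova_p") <- pf(Fstat, kg - 1, df, lower.tail = FALSE)
  attr(out, "mse") <- mse
  out
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons (raw data only)
#'
#' Thin raw-data operation: `stats::kruskal.test` for the omnibus test, then
#' Dunn's rank-sum z statistics with tie correction and Bonferroni-style
#' multiplicity adjustment over the requested comparisons.
#'
#' @param groups named list of raw numeric vectors.
#' @param control optional control label: compare every group to it
#'   (otherwise all pairs).
#' @return list: `kruskal` (htest), `comparisons` (data.frame with z,
#'   p_unadjusted, p_adjusted).
#' @export
kruskal_dunn <- function(groups, control = NULL) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  tie_tab <- table(x)
  tie_corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  rbar <- tapply(r, g, mean)
  ns <- lengths(groups)
  labs <- names(groups)
  prs <- if (is.null(control)) utils::combn(labs, 2, simplify = FALSE)
         else lapply(setdiff(labs, control), function(l) c(control, l))
  m <- length(prs)
  rows <- lapply(prs, function(pr) {
    se <- sqrt(N * (N + 1) / 12 * tie_corr * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste(pr[2], "vs", pr[1]), z = as.numeric(z),
               p_unadjusted = p, p_adjusted = min(1, p * m))
  })
  list(kruskal = kw, comparisons = do.call(rbind, rows))
}
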