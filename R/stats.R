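#' Descriptive summary of a sample
#'
#' Mean, sample SD, coefficient of variation (SD/mean, reported only when
#' the mean is positive), median and the 10/25/75/90 percentiles matching
#' the box-plot convention (boxes 75/25, whiskers 90/10).
#'
#' @param values numeric vector (nonempty, finite).
#' @return one-row tibble.
#' @export
describe_values <- function(values) {
  if (!length(values)) abort("empty input")
  if (any(!is.finite(values))) abort("values must be finite")
  m <- mean(values); s <- sd(values)
  if (length(values) == 1L) s <- 0
  q <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  tibble(n = length(values), mean = m, sd = s,
         cv = if (m > 0) s / m else NA_real_,
         median = median(values), p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4])
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 (S^2 + K^2/4)` with sample skewness `S` and excess kurtosis
#' `K`, referred to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric vector (n >= 3, non-constant).
#' @return one-row tibble with `statistic` and `p.value`.
#' @export
jarque_bera_test <- function(x) {
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(tibble(statistic = NA_real_, p.value = NA_real_))
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2 - 3
  jb <- n / 6 * (skew^2 + kurt^2 / 4)
  tibble(statistic = jb, p.value = pchisq(jb, df = 2, lower.tail = FALSE))
}

# Kolmogorov-Smirnov against a normal with moments estimated from the data
ks_normal_p <- function(x) {
  if (sd(x) == 0) return(NA_real_)
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
}

# both normality tests pass at alpha for every supplied group?
groups_normal <- function(groups, alpha) {
  all(vapply(groups, function(g) {
    jb <- jarque_bera_test(g)$p.value
    ks <- ks_normal_p(g)
    !is.na(jb) && !is.na(ks) && jb > alpha && ks > alpha
  }, logical(1)))
}

#' Significance stars
#'
#' `n.s.` for p >= 0.05, then `*` < 0.05, `**` < 0.01, `***` < 0.001,
#' `****` < 0.0001.
#'
#' @param p p-value(s).
#' @return character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s."), right = FALSE) |>
    as.character()
}

#' Two-group comparison with automatic test selection
#'
#' Runs the Jarque-Bera and Kolmogorov-Smirnov normality tests on each
#' group and an F-test for variance equality; a (paired or unpaired)
#' two-tailed Student's t-test is used when both groups pass both
#' normality tests (alpha = 0.05) and the variances are equal, otherwise a
#' Mann-Whitney-Wilcoxon test.
#'
#' @param x,y the two samples (n >= 3 each; equal length when paired).
#' @param paired paired design?
#' @param alpha gate level for the assumption tests.
#' @return object of class `group_test`; see [generics::tidy()] and
#'   [generics::glance()].
#' @export
compare_two_groups <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) abort("need n >= 3 per group")
  if (paired && length(x) != length(y)) abort("paired samples must match in length")
  if (paired && all(x == y)) {
    report <- list(test = "paired t-test (degenerate: zero differences)",
                   route = "degenerate", statistic = 0, p.value = 1,
                   normality = NULL, var_p = NA_real_,
                   groups = list(x = x, y = y), paired = paired)
    class(report) <- "group_test"
    return(report)
  }
  norm_tb <- tibble(
    group = c("x", "y"),
    jarque_bera_p = c(jarque_bera_test(x)$p.value, jarque_bera_test(y)$p.value),
    ks_p = c(ks_normal_p(x), ks_normal_p(y)))
  var_p <- if (sd(x) > 0 && sd(y) > 0) var.test(x, y)$p.value else NA_real_
  normal <- groups_normal(list(x, y), alpha)
  eqvar <- !is.na(var_p) && var_p > alpha
  if (normal && eqvar) {
    ht <- t.test(x, y, paired = paired, var.equal = TRUE)
    test <- if (paired) "paired t-test" else "unpaired t-test"
    route <- "parametric"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = paired))
    test <- "Mann-Whitney-Wilcoxon"
    route <- "nonparametric"
  }
  report <- list(test = test, route = route, statistic = unname(ht$statistic),
                 p.value = ht$p.value, normality = norm_tb, var_p = var_p,
                 groups = list(x = x, y = y), paired = paired)
  class(report) <- "group_test"
  report
}

#' Multi-group comparison with automatic test selection
#'
#' One-way ANOVA with post hoc Tukey HSD when every group passes both
#' normality tests and variances are homogeneous (Bartlett), otherwise
#' Kruskal-Wallis with post hoc Dunn tests (Bonferroni-adjusted). Requires
#' at least 3 groups; use [compare_two_groups()] for two.
#'
#' @param data data frame in long format.
#' @param value,group column names (strings) of the measurement and the
#'   group label.
#' @param alpha gate level for the assumption tests.
#' @return object of class `group_test` with a `posthoc` tibble.
#' @export
compare_multi_groups <- function(data, value = "value", group = "group",
                                 alpha = 0.05) {
  v <- data[[value]]; g <- factor(data[[group]])
  groups <- split(v, g)
  if (length(groups) < 3)
    abort("fewer than 3 groups: use compare_two_groups() for the two-group path")
  if (any(vapply(groups, length, integer(1)) < 3)) abort("need n >= 3 per group")
  norm_tb <- purrr::map_dfr(names(groups), function(nm)
    tibble(group = nm,
           jarque_bera_p = jarque_bera_test(groups[[nm]])$p.value,
           ks_p = ks_normal_p(groups[[nm]])))
  normal <- groups_normal(groups, alpha)
  var_p <- tryCatch(stats::bartlett.test(v, g)$p.value, error = function(e) NA_real_)
  eqvar <- !is.na(var_p) && var_p > alpha
  if (normal && eqvar) {
    fit <- aov(v ~ g)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    posthoc <- tibble(comparison = rownames(tk), estimate = tk[, "diff"],
                      p.adj = tk[, "p adj"])
    report <- list(test = "one-way ANOVA + Tukey HSD", route = "parametric",
                   statistic = an[1, "F value"], p.value = an[1, "Pr(>F)"],
                   normality = norm_tb, var_p = var_p, posthoc = posthoc,
                   groups = groups)
  } else {
    kw <- kruskal.test(v, g)
    posthoc <- dunn_posthoc(v, g)
    report <- list(test = "Kruskal-Wallis + Dunn", route = "nonparametric",
                   statistic = unname(kw$statistic), p.value = kw$p.value,
                   normality = norm_tb, var_p = var_p, posthoc = posthoc,
                   groups = groups)
  }
  class(report) <- "group_test"
  report
}

#' Dunn's post hoc test
#'
#' All pairwise rank comparisons after a Kruskal-Wallis test, with the
#' tie-corrected z statistic and Bonferroni adjustment over all pairs.
#'
#' @param values numeric vector.
#' @param groups factor of group labels.
#' @param method p-adjustment method (default `"bonferroni"`).
#' @return tibble with `comparison`, `z`, `p.value`, `p.adj`.
#' @export
dunn_posthoc <- function(values, groups, method = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  nn <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[[a]] + 1 / nn[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble(comparison = paste(a, b, sep = "-"), z = z,
           p.value = 2 * pnorm(-abs(z)))
  })
  out$p.adj <- pmin(p.adjust(out$p.value, method = method), 1)
  out
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s (route: %s)\n", x$test, x$route))
  cat(sprintf("  statistic = %.4g, p = %.4g %s\n", x$statistic, x$p.value,
              significance_stars(x$p.value)))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @export
tidy.group_test <- function(x, ...) {
  if (!is.null(x$posthoc))
    return(x$posthoc |> mutate(stars = significance_stars(.data$p.adj)))
  tibble(test = x$test, statistic = x$statistic, p.value = x$p.value,
         stars = significance_stars(x$p.value))
}

#' @export
glance.group_test <- function(x, ...) {
  ns <- vapply(x$groups, length, integer(1))
  tibble(test = x$test, route = x$route, statistic = x$statistic,
         p.value = x$p.value, n_groups = length(x$groups),
         n_total = sum(ns), var_p = x$var_p)
}
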