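# ANOVA / MANOVA / rank-correlation layer. Model fitting goes through stats
# and car; effect sizes and post hoc power use the package's conversions.

new_test_summary <- function(statistic, stat_name, df, p, cohen_d,
                             posthoc_power, correction = "none",
                             extra = list()) {
  structure(c(list(statistic = statistic, stat_name = stat_name, df = df,
                   p = p, cohen_d = cohen_d, posthoc_power = posthoc_power,
                   correction = correction), extra),
            class = "test_summary")
}

#' @export
print.test_summary <- function(x, ...) {
  cat(sprintf("<test_summary: %s(%s) = %.4g, p = %.4g, d = %.3g, power = %.3g%s>\n",
              x$stat_name, paste(x$df, collapse = ","), x$statistic, x$p,
              x$cohen_d, x$posthoc_power,
              if (x$correction != "none") paste0(", ", x$correction) else ""))
  invisible(x)
}

#' One-way ANOVA with eta-squared effect size and post hoc power
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 levels, >= 2 observations each).
#' @param alpha Significance level for the power approximation.
#' @return A `test_summary` (F statistic, df, p, d from eta-squared, power
#'   via the equal-group-size two-sample approximation on the total n).
#' @export
anova_oneway <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_config("need at least 2 groups")
  if (any(table(groups) < 2L)) stop_config("each group needs >= 2 observations")
  if (var(values) == 0) stop_config("response is constant; F undefined")
  fit <- anova(lm(values ~ groups))
  f <- fit$`F value`[1]; df1 <- fit$Df[1]; df2 <- fit$Df[2]
  d <- d_from_f(f, df1, df2)
  n <- length(values)
  new_test_summary(f, "F", c(df1, df2), fit$`Pr(>F)`[1], d,
                   power_two_sample(d, n / 2, n / 2, alpha, equal_n = TRUE))
}

#' Two-way ANOVA (Type-II sums of squares) per effect
#'
#' Fits `values ~ factorA * factorB` and extracts each effect with Type-II
#' sums of squares (suited to the unbalanced two-factor design). Cohen's d
#' per effect comes from partial eta-squared; post hoc power uses the
#' marginal group sizes of that factor (interaction: equal split).
#'
#' @param values Numeric response.
#' @param factorA,factorB Factors (e.g. structure and anesthesia).
#' @param alpha Significance level for the power approximation.
#' @param equal_n_power Use the equal-group-size power mode (default `FALSE`).
#' @return Named list of `test_summary` objects: `factorA`, `factorB`,
#'   `interaction`.
#' @export
anova_twoway <- function(values, factorA, factorB, alpha = 0.05,
                         equal_n_power = FALSE) {
  factorA <- factor(factorA); factorB <- factor(factorB)
  if (any(table(factorA, factorB) < 2L)) {
    stop_config("each cell needs >= 2 observations")
  }
  fit <- car::Anova(lm(values ~ factorA * factorB), type = 2)
  df_res <- fit$Df[rownames(fit) == "Residuals"]
  get_effect <- function(row, ns) {
    f <- fit$`F value`[row]; df1 <- fit$Df[row]
    d <- d_from_f(f, df1, df_res)
    pw <- power_two_sample(d, ns[1], ns[2], alpha, equal_n = equal_n_power)
    new_test_summary(f, "F", c(df1, df_res), fit$`Pr(>F)`[row], d, pw)
  }
  nA <- as.numeric(table(factorA)); nB <- as.numeric(table(factorB))
  n <- length(values)
  list(factorA = get_effect(1L, if (length(nA) == 2L) nA else rep(n / 2, 2)),
       factorB = get_effect(2L, if (length(nB) == 2L) nB else rep(n / 2, 2)),
       interaction = get_effect(3L, rep(n / 2, 2)))
}

#' MANOVA on multivariate observations (Wilks' lambda)
#'
#' Wilks' lambda `det(W)/det(W + B)` with within/between scatter matrices,
#' via [stats::manova()], plus the Rao F approximation, effect size from the
#' multivariate eta-squared, and equal-split post hoc power.
#'
#' @param xyz Numeric matrix (observations x dimensions).
#' @param groups Grouping factor.
#' @param alpha Significance level for the power approximation.
#' @return A `test_summary` with `statistic` = Wilks' lambda and extra fields
#'   `approx_f` and `f_df`.
#' @export
manova_groups <- function(xyz, groups, alpha = 0.05) {
  xyz <- as.matrix(xyz)
  groups <- factor(groups)
  p <- ncol(xyz); g <- nlevels(groups)
  if (any(table(groups) < p + 1L)) {
    stop_config("each group needs at least p + 1 observations")
  }
  fit <- summary(stats::manova(xyz ~ groups), test = "Wilks")
  row <- fit$stats["groups", ]
  lambda <- row[["Wilks"]]
  if (!is.finite(lambda)) stop_config("singular scatter matrices")
  d <- d_from_wilks(lambda, p, g)
  n <- nrow(xyz)
  new_test_summary(lambda, "Wilks", c(row[["num Df"]], row[["den Df"]]),
                   row[["Pr(>F)"]], d,
                   power_two_sample(d, n / 2, n / 2, alpha, equal_n = TRUE),
                   extra = list(approx_f = row[["approx F"]],
                                f_df = c(row[["num Df"]], row[["den Df"]])))
}

#' Spearman rank correlation with Bonferroni correction
#'
#' Average ranks for ties; the p-value uses the t approximation
#' ([stats::cor.test()], `exact = FALSE`) and is multiplied by
#' `n_comparisons` (capped at 1).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @param alpha Significance level for the power approximation.
#' @return A `test_summary` with `statistic` = rho.
#' @export
spearman_cor <- function(x, y, n_comparisons = 1L, alpha = 0.05) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (length(x) < 4L) stop_config("need at least 4 pairs")
  if (var(x) == 0 || var(y) == 0) stop_config("constant input; rho undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  p <- bonferroni(ct$p.value, n_comparisons)
  new_test_summary(rho, "rho", length(x) - 2L, p, d_from_r(rho),
                   power_correlation(rho, length(x), alpha),
                   correction = if (n_comparisons > 1L) "bonferroni" else "none",
                   extra = list(n = length(x)))
}

#' Pairwise post hoc t-tests with Bonferroni correction
#'
#' Welch t-tests between all group pairs, Bonferroni-multiplied by `m`
#' (default: the number of pairs).
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @param m Bonferroni multiplier.
#' @return Data frame: `group1`, `group2`, `t`, `p_raw`, `p_corrected`, `d`.
#' @export
posthoc_ttests <- function(values, groups, m = NULL) {
  groups <- factor(groups)
  pairs <- combn(levels(groups), 2L)
  m <- m %||% ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- values[groups == pairs[1, k]]
    b <- values[groups == pairs[2, k]]
    tt <- t.test(a, b)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_corrected = bonferroni(tt$p.value, m),
               d = cohen_d_two_sample(a, b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
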