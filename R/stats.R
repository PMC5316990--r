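# The statistical battery used for group comparisons: normality screening,
# variance-equality screening with a log(value + 1) variance-stabilizing
# transform, Kruskal-Wallis with Dunn's post hoc, one-way ANOVA with
# Dunnett's or Tukey's post hoc, Fisher's exact test, two-sample
# Kolmogorov-Smirnov, and robust FDR-based outlier elimination for
# one-sample data.
#
# Standard tests are delegated to the stats/car/multcomp machinery; Dunn's
# rank-based post hoc and the robust outlier rule are implemented here.

new_sg_test <- function(method, statistic, df, p.value, posthoc = NULL,
                        extra = NULL) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p.value = p.value, posthoc = posthoc), extra),
            class = "sg_test")
}

#' @export
print.sg_test <- function(x, ...) {
  dfs <- if (length(x$df) == 2)
    sprintf("(%g, %g)", x$df[1], x$df[2])
  else if (length(x$df) == 1 && is.finite(x$df)) sprintf("(%g)", x$df)
  else ""
  cat(sprintf("%s: statistic%s = %.4g, p = %.4g\n",
              x$method, dfs, x$statistic, x$p.value))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' log(value + 1) transform
#'
#' Natural-log variance-stabilizing transform applied to percentage data
#' before parametric testing when group variances are unequal.
#'
#' @param values Numeric vector, all > -1 (percentages are >= 0).
#' @return Transformed values; invert with `expm1`.
#' @export
log1p_transform <- function(values) {
  if (any(values < -1 | !is.finite(values)))
    stop("values must be finite and > -1")
  log1p(values)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test against a normal distribution with the sample's mean
#' and SD.
#'
#' @param values Numeric vector (>= 5 values).
#' @return An `sg_test` with statistic `D`.
#' @export
ks_normality <- function(values) {
  if (length(values) < 5) stop("need at least 5 values")
  if (sd(values) == 0) stop("degenerate sample (zero variance)")
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  new_sg_test("Kolmogorov-Smirnov normality", unname(kt$statistic), NA_real_,
              kt$p.value)
}

#' Brown-Forsythe test for equality of variances
#'
#' One-way ANOVA on absolute deviations from group medians.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels.
#' @return An `sg_test` with the F statistic and (df1, df2).
#' @export
brown_forsythe <- function(values, groups) {
  groups <- factor(groups)
  if (any(tapply(values, groups, length) < 2))
    stop("each group needs at least 2 values")
  lt <- car::leveneTest(values, groups, center = median)
  new_sg_test("Brown-Forsythe", lt$`F value`[1],
              c(lt$Df[1], lt$Df[2]), lt$`Pr(>F)`[1])
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected H statistic with a chi-square p value; Dunn's z statistics
#' on rank means for every group pair, with a family-wise adjustment
#' (Bonferroni by default).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]. Default
#'   `"bonferroni"`.
#' @param control Optional control-group label: restrict Dunn comparisons to
#'   control vs others.
#' @return An `sg_test` with `H`, df, p, and a post hoc table.
#' @export
kruskal_wallis <- function(values, groups, p_adjust = "bonferroni",
                           control = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  kt <- kruskal.test(values, groups)
  ph <- dunn_posthoc(values, groups, p_adjust, control)
  new_sg_test("Kruskal-Wallis", unname(kt$statistic),
              unname(kt$parameter), kt$p.value, posthoc = ph)
}

# Dunn's rank-based many/all comparisons with tie correction
dunn_posthoc <- function(values, groups, p_adjust = "bonferroni",
                         control = NULL) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  levs <- levels(groups)
  pairs <- if (is.null(control)) utils::combn(levs, 2, simplify = FALSE)
  else lapply(setdiff(levs, control), function(g) c(control, g))
  rows <- lapply(pairs, function(pr) {
    z <- abs(rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(s2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    data.frame(group1 = pr[1], group2 = pr[2], z = unname(z),
               p = 2 * pnorm(-abs(unname(z))))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, p.adjust(out$p, method = p_adjust))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Dunnett's or Tukey's post hoc comparisons
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels.
#' @param posthoc `"dunnett"` (many-to-one against `control`) or `"tukey"`
#'   (all pairs).
#' @param control Control-group label for Dunnett comparisons; defaults to
#'   the first factor level.
#' @return An `sg_test` with the F statistic, (df1, df2), p and a post hoc
#'   table of adjusted p values.
#' @export
one_way_anova <- function(values, groups, posthoc = c("dunnett", "tukey"),
                          control = NULL) {
  posthoc <- match.arg(posthoc)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tapply(values, groups, length) < 2))
    stop("each group needs at least 2 values")
  if (all(tapply(values, groups, var) == 0))
    stop("zero within-group variance everywhere")
  if (!is.null(control)) groups <- stats::relevel(groups, ref = control)
  d <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  ph <- if (posthoc == "tukey") {
    tk <- TukeyHSD(fit)$g
    data.frame(comparison = rownames(tk), diff = tk[, "diff"],
               p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    data.frame(comparison = names(sm$test$coefficients),
               diff = unname(sm$test$coefficients),
               p_adj = unname(sm$test$pvalues), row.names = NULL)
  }
  new_sg_test("One-way ANOVA", an$`F value`[1], c(an$Df[1], an$Df[2]),
              an$`Pr(>F)`[1], posthoc = ph)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p: the sum of hypergeometric probabilities of all tables with
#' the observed margins that are no more probable than the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return An `sg_test` (statistic = odds-ratio estimate).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(new_sg_test("Fisher exact", NA_real_, NA_real_, 1))
  ft <- fisher.test(table)
  new_sg_test("Fisher exact", unname(ft$estimate), NA_real_, ft$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b Numeric samples.
#' @return An `sg_test` with `D` = maximum ECDF gap and the asymptotic p.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  kt <- suppressWarnings(ks.test(a, b))
  new_sg_test("Two-sample Kolmogorov-Smirnov", unname(kt$statistic),
              NA_real_, kt$p.value)
}

#' Robust FDR-based outlier elimination (one-sample)
#'
#' Robust-regression-and-outlier-removal style rule for a single sample:
#' residuals are taken from the median, the robust scale is the 68.27th
#' percentile of absolute residuals with a small-sample correction
#' (`n/(n-1)`), and points are flagged outliers when their two-tailed
#' t-probability falls below the FDR boundary at rate `q`, testing the
#' largest residuals first and stopping at the first non-significant point.
#'
#' @param values Numeric sample (>= 5 values for any removal).
#' @param q False-discovery rate. Default 0.01.
#' @return List: `kept`, `outliers`, `flag` (logical per input value),
#'   `scale` (robust SD analog).
#' @export
rout_outliers <- function(values, q = 0.01) {
  stopifnot(q > 0, q < 1)
  n <- length(values)
  if (n < 5) {
    warning("fewer than 5 values; no outlier removal attempted")
    return(list(kept = values, outliers = values[0],
                flag = rep(FALSE, n), scale = NA_real_))
  }
  res <- values - median(values)
  rsdr <- quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  flag <- rep(FALSE, n)
  if (rsdr > 0) {
    ord <- order(-abs(res))
    p <- 2 * pt(-abs(res) / rsdr, df = n - 1)
    for (i in seq_len(n)) {
      alpha_i <- q * (n - i + 1) / n
      if (p[ord[i]] < alpha_i) flag[ord[i]] <- TRUE else break
    }
  }
  list(kept = values[!flag], outliers = values[flag], flag = flag,
       scale = rsdr)
}

#' Automatic group comparison driver
#'
#' Mirrors the decision pipeline used for the group comparisons: screen each
#' group for normality (KS); if any group is non-normal use Kruskal-Wallis
#' with Dunn's post hoc; otherwise screen variances (Brown-Forsythe) and, if
#' unequal, apply the log(value + 1) transform before a one-way ANOVA with
#' the requested post hoc.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels.
#' @param alpha Screening significance level. Default 0.05.
#' @param posthoc Post hoc for the ANOVA branch. Default `"dunnett"`.
#' @param control Control label for many-to-one comparisons.
#' @return An `sg_test`; the `route` element records the branch taken
#'   (`"kruskal"`, `"anova"`, `"anova_log1p"`).
#' @export
auto_compare_groups <- function(values, groups, alpha = 0.05,
                                posthoc = "dunnett", control = NULL) {
  groups <- factor(groups)
  norm_p <- vapply(split(values, groups),
                   function(v) ks_normality(v)$p.value, numeric(1))
  if (any(norm_p < alpha)) {
    out <- kruskal_wallis(values, groups, control = control)
    out$route <- "kruskal"
    return(out)
  }
  bf <- brown_forsythe(values, groups)
  if (bf$p.value < alpha && all(values > -1)) {
    out <- one_way_anova(log1p_transform(values), groups, posthoc = posthoc,
                         control = control)
    out$route <- "anova_log1p"
  } else {
    out <- one_way_anova(values, groups, posthoc = posthoc,
                         control = control)
    out$route <- "anova"
  }
  out
}
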