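# Weekly trend modelling and group comparisons. Metrics aggregated per FOV
# are fitted against week and week^2 by maximum likelihood,
# y = k + m*x + n*x^2, so nonlinear maturation dynamics can be studied with
# linear methods: the rate y' = m + 2nx crosses zero at the inflection week
# -m/(2n), and the sign of n separates accelerating (n > 0) from
# decelerating dynamics. A strictly linear fit is produced alongside for
# pseudo-R2 / AIC model comparison.

#' Fit the quadratic week-trend GLM
#'
#' Fits `y ~ week + week^2` by maximum likelihood (`stats::glm`), Gaussian
#' with identity link for continuous metrics or Poisson with log link for
#' counts, plus the strictly linear comparison model. Reports coefficients
#' (k, m, n), standard errors, Wald p-values, deviance-based pseudo-R2, AIC of
#' both models, and the inflection week.
#'
#' @param y response values (one per observation, e.g. per FOV).
#' @param week week of each observation; at least 3 distinct values.
#' @param family `"gaussian"` or `"poisson"`. Counts with non-integer
#'   FOV means are fitted as Gaussian unless `family = "poisson"` is forced
#'   with integer-rounded values.
#' @param metric optional metric name carried into the output.
#' @return object of class `glm_quad_fit`.
#' @examples
#' f <- fit_quadratic_glm(c(1, 2, 4, 7), 1:4)
#' coef(f)
#' @export
fit_quadratic_glm <- function(y, week, family = c("gaussian", "poisson"),
                              metric = NULL) {
  family <- match.arg(family)
  if (length(y) != length(week)) stop("y and week lengths differ")
  keep <- is.finite(y) & is.finite(week)
  y <- y[keep]; week <- week[keep]
  if (length(unique(week)) < 3L)
    stop("at least 3 distinct week values are required")
  fam <- if (family == "gaussian") stats::gaussian()
  else stats::poisson()
  if (family == "poisson") y <- round(y)
  df <- data.frame(y = y, x = week)
  fit2 <- stats::glm(y ~ x + I(x^2), data = df, family = fam)
  fit1 <- stats::glm(y ~ x, data = df, family = fam)
  fit0 <- stats::glm(y ~ 1, data = df, family = fam)
  sm <- summary(fit2)$coefficients
  co <- stats::coef(fit2)
  # deviance-based pseudo-R2 (equals classical R2 for gaussian/identity;
  # stays in [0, 1] where the likelihood-ratio form does not)
  pr2 <- function(f) 1 - f$deviance / fit0$deviance
  n_coef <- co[["I(x^2)"]]
  m_coef <- co[["x"]]
  out <- list(
    metric = metric, family = family,
    k = co[["(Intercept)"]], m = m_coef, n = n_coef,
    se = sm[, "Std. Error"], p = sm[, ncol(sm)],
    converged = fit2$converged,
    aic = stats::AIC(fit2), aic_linear = stats::AIC(fit1),
    pseudo_r2 = pr2(fit2), pseudo_r2_linear = pr2(fit1),
    inflection = if (abs(n_coef) > 0) -m_coef / (2 * n_coef) else NA_real_,
    dynamics = if (n_coef > 0) "accelerating"
    else if (n_coef < 0) "decelerating" else "linear",
    glm = fit2, glm_linear = fit1, n_obs = length(y))
  class(out) <- "glm_quad_fit"
  out
}

#' @export
coef.glm_quad_fit <- function(object, ...) {
  c(k = object$k, m = object$m, n = object$n)
}

#' @export
predict.glm_quad_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$glm, type = "response"))
  if (is.numeric(newdata)) newdata <- data.frame(x = newdata)
  stats::predict(object$glm, newdata = newdata, type = "response")
}

#' @export
print.glm_quad_fit <- function(x, ...) {
  cat(sprintf("quadratic %s GLM%s: y = %.4g + %.4g x + %.4g x^2\n",
              x$family,
              if (is.null(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$k, x$m, x$n))
  cat(sprintf("  %s dynamics; inflection at week %.3g\n", x$dynamics,
              x$inflection))
  cat(sprintf("  AIC %.2f (linear %.2f); pseudo-R2 %.3f (linear %.3f); n = %d\n",
              x$aic, x$aic_linear, x$pseudo_r2, x$pseudo_r2_linear, x$n_obs))
  invisible(x)
}

#' @export
summary.glm_quad_fit <- function(object, ...) {
  print(object)
  cat("\ncoefficients:\n")
  tab <- cbind(estimate = coef(object), se = object$se, p = object$p)
  rownames(tab) <- c("k", "m", "n")
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  invisible(tab)
}

#' Inflection point of a fitted quadratic trend
#'
#' The week at which the rate of change y' = m + 2nx crosses zero:
#' -m / (2n). `NA` when the quadratic term is zero. Positive n means
#' accelerating dynamics, negative decelerating.
#'
#' @param fit a `glm_quad_fit`, or a list/vector with elements `m` and `n`.
#' @return list with `week` and `dynamics`.
#' @export
inflection_point <- function(fit) {
  m <- if (is.list(fit)) fit$m else fit[["m"]]
  n <- if (is.list(fit)) fit$n else fit[["n"]]
  if (is.na(n) || n == 0)
    return(list(week = NA_real_, dynamics = "linear"))
  list(week = -m / (2 * n),
       dynamics = if (n > 0) "accelerating" else "decelerating")
}

#' Significance stars
#'
#' Figure-legend convention: `***` p < 0.005, `**` p < 0.01, `*` p < 0.05.
#'
#' @param p p-value vector.
#' @param cutoffs decreasing cutoffs for one, two, three stars.
#' @return character vector.
#' @export
significance_stars <- function(p, cutoffs = c(0.05, 0.01, 0.005)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    paste(rep("*", sum(pi < cutoffs)), collapse = "")
  }, character(1))
}

#' Two-sided Welch's t-test
#'
#' Compares two sample means without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom). Thin wrapper over
#' [stats::t.test()] returning the package's test-result shape.
#'
#' @param a,b numeric samples (>= 2 values each, nonzero variance).
#' @return list with `statistic`, `df`, `p`, `stars`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("samples need >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = significance_stars(tt$p.value),
       mean_a = mean(a), mean_b = mean(b))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' F-test for variance between timepoint groups, followed by Tukey's honest
#' significant difference test (95 percent family-wise confidence) for all
#' pairs, via [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups with >= 2 values each).
#' @return list with `f`, `df`, `p`, and `pairwise` data.frame (pair, diff,
#'   adjusted p, stars).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 values")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$groups
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   p_adj = tk[, "p adj"],
                   stars = significance_stars(tk[, "p adj"]),
                   row.names = NULL)
  list(f = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
       p = an[1, "Pr(>F)"], pairwise = pw)
}

#' Shapiro-Wilk normality check
#'
#' Delegates to [stats::shapiro.test()]; recorded in provenance only (the
#' downstream tests are run regardless of the outcome).
#'
#' @param sample numeric vector, 3 to 5000 values, non-constant.
#' @return p-value.
#' @export
normality_check <- function(sample) {
  if (length(sample) < 3L || length(sample) > 5000L)
    stop("sample size must be in [3, 5000]")
  if (stats::var(sample) == 0) stop("constant sample")
  stats::shapiro.test(sample)$p.value
}

#' Fit week trends for every metric of an FOV summary table
#'
#' Runs [fit_quadratic_glm()] per metric column (and per treatment when a
#' `treatment` column is present); `count` is fitted as Poisson, everything
#' else Gaussian.
#'
#' @param fovs FOV summary table with a `week` column.
#' @param metrics metric columns to fit (default: all numeric except keys).
#' @return data.frame, one row per metric (x treatment): k, m, n, p-values,
#'   AICs, pseudo-R2, inflection.
#' @export
fit_trend_table <- function(fovs, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- names(fovs)[vapply(fovs, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("fov", "week", "n_cells"))
  }
  arms <- if ("treatment" %in% names(fovs)) unique(fovs$treatment) else NA
  rows <- list()
  for (arm in arms) {
    sub <- if (is.na(arm[1])) fovs else fovs[fovs$treatment == arm, ]
    for (m in metrics) {
      fam <- if (m == "count") "poisson" else "gaussian"
      f <- try(fit_quadratic_glm(sub[[m]], sub$week, family = fam,
                                 metric = m), silent = TRUE)
      if (inherits(f, "try-error")) next
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = arm, metric = m, family = f$family,
        k = f$k, m = f$m, n = f$n,
        p_m = f$p[2], p_n = f$p[3],
        aic = f$aic, aic_linear = f$aic_linear,
        pseudo_r2 = f$pseudo_r2, inflection = f$inflection,
        dynamics = f$dynamics)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
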