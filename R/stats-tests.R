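# Group-comparison statistics used across the pipeline. All of these wrap
# the corresponding base-R machinery; what the pipeline adds is the exact/
# approximate switching policy, the zero-variance conventions and the
# separation reporting that qPCR-sized cohorts need.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value by enumeration of rank assignments when the two groups
#' together hold at most 12 observations and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `a` relative to `b`.
#' @return A `zygo_test` list: `statistic` (the U statistic for `a`),
#'   `p.value`, `method`, `exact`, `alternative`, `n`.
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  structure(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                 method = "Mann-Whitney U", exact = exact,
                 alternative = alternative,
                 n = c(length(a), length(b))),
            class = "zygo_test")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' tables (with the observed margins) at most as probable as the observed
#' one. A table with a zero margin carries no information and has p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A `zygo_test` list with the conditional odds-ratio estimate as
#'   `statistic`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) ||
      any(table != round(table)))
    stop("`table` must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  ht <- stats::fisher.test(table, alternative = "two.sided")
  structure(list(statistic = unname(ht$estimate), p.value = ht$p.value,
                 method = "Fisher exact (two-sided)", exact = TRUE,
                 alternative = "two.sided", n = sum(table)),
            class = "zygo_test")
}

#' @export
print.zygo_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %s)\n",
              x$method, x$statistic, x$p.value,
              if (isTRUE(x$exact)) "exact" else "approximate",
              paste(x$n, collapse = "+")))
  invisible(x)
}

# One-way ANOVA p-value with the pipeline's conventions:
#  - zero total variance (no signal at all) -> p = 1;
#  - zero residual variance with real group differences -> p = 0;
#  - returns NA when fewer than 2 usable groups or no residual df.
.anova_p <- function(values, groups, var_equal = TRUE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) return(NA_real_)
  if (length(values) - nlevels(groups) < 1) return(NA_real_)
  tot_var <- stats::var(values)
  if (!is.finite(tot_var) || tot_var < 1e-24) return(1)
  res_var <- sum(tapply(values, groups, function(v) {
    if (length(v) < 2) 0 else stats::var(v) * (length(v) - 1)
  }))
  if (res_var < 1e-24) return(0)
  if (var_equal && any(tapply(values, groups, length) < 2)) {
    # classic fixed-effects ANOVA tolerates singleton groups
    fit <- stats::anova(stats::lm(values ~ groups))
    return(fit[["Pr(>F)"]][1])
  }
  stats::oneway.test(values ~ groups, var.equal = var_equal)$p.value
}

#' Univariate logistic regression of a binary outcome on one factor
#'
#' Maximum-likelihood fit of `outcome ~ factor` with reference coding and
#' per-level Wald p-values. Complete or quasi-complete separation (some
#' level predicts the outcome perfectly) leaves the likelihood without a
#' finite maximizer; it is detected from the fitted probabilities and
#' reported as non-estimable rather than returning the arbitrarily large
#' coefficient the optimizer stopped at.
#'
#' @param outcome Binary vector (logical, 0/1, or 2-level factor) with at
#'   least one event and one non-event.
#' @param factor_values Vector (binary or categorical) of the same length.
#' @return A list of class `zygo_logistic`: `coefficients` data frame
#'   (`level`, `estimate`, `se`, `p.value`), `separation` flag, `n`.
#' @export
univariate_logistic <- function(outcome, factor_values) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  keep <- !is.na(y) & !is.na(factor_values)
  y <- y[keep]
  x <- factor(factor_values[keep])
  if (length(unique(y)) < 2)
    stop("outcome is constant; logistic regression undefined", call. = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  mu <- stats::fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  sm <- summary(fit)$coefficients
  co <- data.frame(level = sub("^x", "", rownames(sm)),
                   estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"],
                   p.value = sm[, "Pr(>|z|)"], row.names = NULL)
  if (separation) {
    co$estimate <- NA_real_
    co$se <- NA_real_
    co$p.value <- NA_real_
  }
  structure(list(coefficients = co, separation = separation,
                 n = length(y), method = "univariate logistic (Wald)"),
            class = "zygo_logistic")
}

#' @export
print.zygo_logistic <- function(x, ...) {
  cat(sprintf("%s, n = %d%s\n", x$method, x$n,
              if (x$separation) " [separation: not estimable]" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Dichotomize clinical factors at fixed cutpoints
#'
#' Cuts numeric clinical variables into two strata at the conventional
#' GIST cutpoints — 60 years for age, 6 cm for tumour size, 2 per 5 mm2
#' for the mitotic count — with the cutpoint itself falling in the high
#' stratum (value >= cutpoint -> `">=<cut>"`). Missing values stay
#' missing; non-numeric entries are a parse error.
#'
#' @param clinical Data frame of raw clinical values.
#' @param cutpoints Named numeric vector mapping column names to
#'   cutpoints; default `c(age = 60, size = 6, mitoses = 2)`. Columns not
#'   named here pass through unchanged.
#' @return The data frame with each cut column replaced by a factor with
#'   levels `"<cut"`, `">=cut"`; cutpoints are recorded in
#'   `attr(, "cutpoints")`.
#' @export
dichotomize_clinical <- function(clinical,
                                 cutpoints = c(age = 60, size = 6,
                                               mitoses = 2)) {
  clinical <- as.data.frame(clinical)
  for (col in intersect(names(cutpoints), names(clinical))) {
    raw <- clinical[[col]]
    if (!is.numeric(raw)) {
      num <- suppressWarnings(as.numeric(as.character(raw)))
      bad <- !is.na(raw) & as.character(raw) != "" & is.na(num)
      if (any(bad))
        stop(sprintf("non-numeric value in clinical factor '%s': '%s'",
                     col, as.character(raw)[bad][1]), call. = FALSE)
      raw <- num
    }
    cut_at <- cutpoints[[col]]
    lv <- c(sprintf("<%g", cut_at), sprintf(">=%g", cut_at))
    clinical[[col]] <- factor(ifelse(is.na(raw), NA,
                                     ifelse(raw >= cut_at, lv[2], lv[1])),
                              levels = lv)
  }
  attr(clinical, "cutpoints") <- cutpoints
  clinical
}
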