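#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square (no continuity correction) with
#' df = (r - 1)(c - 1).
#'
#' @param table r x c matrix of nonnegative counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_counts <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' One-way ANOVA with pairwise pooled t tests
#'
#' Tests for differences in a feature across cohorts with a one-way ANOVA
#' (df = k - 1, N - k), then computes all pairwise independent t tests. The
#' pairwise tests use pooled variance by default, so df = n1 + n2 - 2;
#' `var_equal = FALSE` switches to Welch. Cohort means and SDs are reported
#' alongside.
#'
#' @param values Numeric feature vector.
#' @param groups Grouping vector (cohort labels), same length.
#' @param feature Optional feature name carried into the result.
#' @param var_equal Pooled-variance pairwise t tests (default) or Welch.
#' @return A `group_comparison` object: list with `feature`, `anova`
#'   (F, df1, df2, p), `pairwise` (data.frame), `summary` (per-group n,
#'   mean, sd).
#' @export
anova_and_pairwise <- function(values, groups, feature = NA_character_,
                               var_equal = TRUE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- groups[ok]
  # keep first-appearance order so pairwise rows read HC/CHR, HC/ROP, ...
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  anova_res <- list(F = tab[["F value"]][1],
                    df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
                    p = tab[["Pr(>F)"]][1])
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  summ <- data.frame(
    group = lev,
    n = as.integer(table(groups)[lev]),
    mean = as.numeric(tapply(values, groups, mean)[lev]),
    sd = as.numeric(tapply(values, groups, stats::sd)[lev]),
    stringsAsFactors = FALSE)
  structure(list(feature = feature, anova = anova_res, pairwise = pw,
                 summary = summ),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$feature, x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix of lexical features
#'
#' Pairwise-complete Pearson correlations; a constant feature yields NA in
#' its row/column (flagged with a warning) rather than an error.
#'
#' @param features data.frame or matrix of numeric columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  m <- as.matrix(features)
  if (nrow(m) < 3L) stop("need at least 3 observations")
  const <- apply(m, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (any(const))
    warning("constant feature(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; correlations undefined")
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(const, NA_real_, 1)
  r
}

#' Standardized multiple linear regression
#'
#' Ordinary least squares of one lexical outcome on a predictor set that may
#' mix continuous variables and categorical ones (cohort, site, racial
#' identity), the latter dummy-coded against stated reference levels.
#' Standardized estimates are obtained by z-scoring the outcome and every
#' predictor column — dummy columns included — and refitting; with
#' `standardize = "outcome_only"` raw estimates are instead divided by the
#' outcome SD only. Raw and standardized fits share t statistics and R^2.
#'
#' @param records data.frame holding outcome and predictors.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names. Character
#'   or factor columns are dummy-coded.
#' @param references Named character vector of reference levels for
#'   categorical predictors, e.g. `c(cohort = "HC", site = "Melbourne")`.
#' @param standardize `"all"` (z-score every column, default) or
#'   `"outcome_only"`.
#' @return A `regression_report`: list with `outcome`, `coefficients`
#'   (data.frame: term, estimate, se, t, p, std_estimate), `r_squared`,
#'   `adj_r_squared`, `n`.
#' @export
standardized_regression <- function(records, outcome, predictors,
                                    references = NULL,
                                    standardize = c("all", "outcome_only")) {
  standardize <- match.arg(standardize)
  stopifnot(outcome %in% names(records), all(predictors %in% names(records)))
  dat <- records[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (p in predictors) {
    if (is.character(dat[[p]]) || is.factor(dat[[p]])) {
      f <- factor(dat[[p]])
      if (!is.null(references) && p %in% names(references))
        f <- stats::relevel(f, ref = references[[p]])
      dat[[p]] <- f
    }
  }
  form <- stats::reformulate(predictors, outcome)
  mm <- stats::model.matrix(form, dat)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  x <- mm[, -1, drop = FALSE]
  y <- dat[[outcome]]
  if (standardize == "all") {
    zs <- function(v) (v - mean(v)) / stats::sd(v)
    zx <- apply(x, 2, zs)
    zfit <- stats::lm(zs(y) ~ zx)
    std_est <- c(NA_real_, unname(stats::coef(zfit)[-1]))
  } else {
    std_est <- c(NA_real_, unname(stats::coef(fit)[-1]) / stats::sd(y))
  }
  coefs <- data.frame(term = rownames(co),
                      estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      t = co[, "t value"],
                      p = co[, "Pr(>|t|)"],
                      std_estimate = std_est,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(outcome = outcome, coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = nrow(dat)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %s: R^2 = %.3f (adj %.3f), n = %d\n",
              x$outcome, x$r_squared, x$adj_r_squared, x$n))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Spearman correlations between lexical features and clinical scores
#'
#' Computes Spearman's rho (midranks under ties) and its p-value for every
#' (feature, score) pair within the requested scope: the combined clinical
#' cohorts (CHR + ROP), one cohort, or one recruitment site's clinical
#' participants. Cells with fewer than 3 complete pairs are reported as
#' missing. Each p is flagged against the Bonferroni-corrected level
#' `alpha / k` where k is the number of tests in the declared family.
#'
#' @param records Participant data.frame with `cohort` and the named columns.
#' @param features Feature column names.
#' @param scores Clinical score column names (e.g. `gf_role`, `gf_social`).
#' @param scope `"clinical"` (CHR + ROP combined, default), a cohort label,
#'   or `NULL` for all rows.
#' @param site Optional site label restricting the scope.
#' @param alpha Family-wise significance level.
#' @param k Number of tests in the Bonferroni family; defaults to the number
#'   of (feature, score) pairs computed here.
#' @return data.frame with columns `feature`, `score`, `rho`, `p`, `n`,
#'   `significant` (at alpha / k).
#' @export
clinical_correlations <- function(records, features,
                                  scores = c("gf_role", "gf_social"),
                                  scope = "clinical", site = NULL,
                                  alpha = 0.05, k = NULL) {
  dat <- records
  if (!is.null(scope)) {
    keep <- if (identical(scope, "clinical")) dat$cohort %in% c("CHR", "ROP")
            else dat$cohort == scope
    dat <- dat[keep, , drop = FALSE]
  }
  if (!is.null(site)) dat <- dat[dat$site == site, , drop = FALSE]
  grid <- expand.grid(feature = features, score = scores,
                      stringsAsFactors = FALSE)
  if (is.null(k)) k <- nrow(grid)
  thr <- bonferroni_alpha(alpha, k)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- dat[[grid$feature[i]]]
    s <- dat[[grid$score[i]]]
    ok <- !is.na(f) & !is.na(s)
    if (sum(ok) < 3L)
      return(data.frame(feature = grid$feature[i], score = grid$score[i],
                        rho = NA_real_, p = NA_real_, n = sum(ok),
                        significant = NA, stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(f[ok], s[ok], method = "spearman"))
    data.frame(feature = grid$feature[i], score = grid$score[i],
               rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               significant = ct$p.value < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni-corrected per-test significance level
#'
#' @param family_alpha Family-wise alpha.
#' @param k Number of tests in the family (k >= 1).
#' @return `family_alpha / k`.
#' @export
bonferroni_alpha <- function(family_alpha, k) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be a positive count")
  family_alpha / k
}
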