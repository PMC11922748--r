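#' Default covariate order for sequential adjustment
#'
#' Sex, age, recruitment site, education, racial identity, socioeconomic
#' status (maternal education as proxy), and IQ in the subset with scores —
#' in that order, each tagged categorical or continuous.
#'
#' @return data.frame with columns `covariate`, `kind`, `subset_ok`.
#' @export
default_covariate_order <- function() {
  data.frame(
    covariate = c("sex", "age", "site", "education", "race",
                  "maternal_education", "iq"),
    kind = c("categorical", "continuous", "categorical", "continuous",
             "categorical", "continuous", "continuous"),
    subset_ok = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Test association between a lexical feature and a covariate
#'
#' Categorical covariates are tested with a two-sided pooled-variance t test
#' (two levels) or a one-way ANOVA (more levels); continuous covariates with
#' a Spearman rank correlation. Incomplete pairs are dropped.
#'
#' @param feature Numeric vector of feature values.
#' @param covariate Vector of covariate values (factor/character for
#'   categorical, numeric for continuous).
#' @param kind `"categorical"` or `"continuous"`.
#' @return List with `statistic`, `p`, `method`, `n`.
#' @export
test_association <- function(feature, covariate,
                             kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  ok <- !is.na(feature) & !is.na(covariate)
  feature <- feature[ok]
  covariate <- covariate[ok]
  if (kind == "categorical") {
    covariate <- factor(covariate)
    covariate <- droplevels(covariate)
    if (nlevels(covariate) < 2L) stop("constant covariate: nothing to test")
    if (any(table(covariate) < 2L))
      stop("need at least 2 observations per category")
    if (stats::sd(feature) == 0)  # identical everywhere: no evidence at all
      return(list(statistic = 0,
                  p = 1,
                  method = if (nlevels(covariate) == 2L) "t" else "anova",
                  n = length(feature)))
    if (nlevels(covariate) == 2L) {
      tt <- stats::t.test(feature ~ covariate, var.equal = TRUE)
      list(statistic = unname(tt$statistic), p = tt$p.value,
           method = "t", n = length(feature))
    } else {
      fit <- stats::aov(feature ~ covariate)
      tab <- summary(fit)[[1]]
      list(statistic = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
           method = "anova", n = length(feature))
    }
  } else {
    if (length(feature) < 3L) stop("need at least 3 complete pairs")
    if (stats::sd(covariate) == 0) stop("constant covariate: nothing to test")
    ct <- suppressWarnings(
      stats::cor.test(feature, covariate, method = "spearman"))
    list(statistic = unname(ct$estimate), p = ct$p.value,
         method = "spearman", n = length(feature))
  }
}

#' Fit an HC-anchored categorical adjustment
#'
#' Computes the median of the feature within each covariate category using
#' healthy-control (HC) records only; every category's offset is its HC
#' median minus the reference category's HC median. Adjusting subtracts the
#' offset of a participant's category from their value, so after adjustment
#' the HC per-category medians are equal. The reference is the largest HC
#' category (any reference yields the same between-group contrasts).
#'
#' @param records Participant data.frame with a `cohort` column.
#' @param feature Name of the numeric feature column.
#' @param covariate Name of the categorical covariate column.
#' @return An `adjustment_model`.
#' @export
fit_categorical_adjustment <- function(records, feature, covariate) {
  hc <- records[records$cohort == "HC" &
                  !is.na(records[[covariate]]) &
                  !is.na(records[[feature]]), , drop = FALSE]
  cats <- unique(stats::na.omit(records[[covariate]]))
  missing_cats <- setdiff(cats, unique(hc[[covariate]]))
  if (length(missing_cats))
    stop("no HC members in category '", paste(missing_cats, collapse = "', '"),
         "' of covariate '", covariate, "'")
  med <- tapply(hc[[feature]], hc[[covariate]], stats::median)
  reference <- names(which.max(table(hc[[covariate]])))
  offsets <- med - med[[reference]]
  structure(list(covariate = covariate, feature = feature,
                 kind = "categorical",
                 offsets = offsets, reference = reference),
            class = "adjustment_model")
}

#' Fit an HC-anchored continuous adjustment
#'
#' Fits an ordinary least-squares line feature ~ covariate on HC records
#' only. Adjusting any participant subtracts the HC-predicted component and
#' re-centers at the HC feature mean:
#' adjusted = value - (predicted(covariate) - mean_HC(feature)),
#' i.e. the HC-model residual put back on the original scale. Participants
#' outside HC are adjusted with the HC-fitted line, never refit.
#'
#' @param records Participant data.frame with a `cohort` column.
#' @param feature Name of the numeric feature column.
#' @param covariate Name of the numeric covariate column.
#' @return An `adjustment_model`.
#' @export
fit_continuous_adjustment <- function(records, feature, covariate) {
  hc <- records[records$cohort == "HC" &
                  !is.na(records[[covariate]]) &
                  !is.na(records[[feature]]), , drop = FALSE]
  if (nrow(hc) < 3L) stop("need at least 3 HC records to fit")
  if (stats::sd(hc[[covariate]]) == 0)
    stop("covariate '", covariate, "' is constant in HC: singular fit")
  fit <- stats::lm(stats::reformulate(covariate, feature), data = hc)
  co <- stats::coef(fit)
  if (any(is.na(co))) stop("singular fit for covariate '", covariate, "'")
  structure(list(covariate = covariate, feature = feature,
                 kind = "continuous",
                 intercept = unname(co[1]), slope = unname(co[2]),
                 hc_mean = mean(hc[[feature]])),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  if (x$kind == "categorical") {
    cat("<adjustment_model> categorical ", x$feature, " ~ ", x$covariate,
        " (reference ", x$reference, ")\n", sep = "")
  } else {
    cat(sprintf("<adjustment_model> continuous %s ~ %s (slope %.4g)\n",
                x$feature, x$covariate, x$slope))
  }
  invisible(x)
}

#' Apply a fitted adjustment model
#'
#' Rows with a missing covariate value are left unchanged.
#'
#' @param model An `adjustment_model`.
#' @param records Participant data.frame containing the model's feature and
#'   covariate columns.
#' @return `records` with the feature column adjusted.
#' @export
apply_adjustment <- function(model, records) {
  stopifnot(inherits(model, "adjustment_model"))
  v <- records[[model$feature]]
  cv <- records[[model$covariate]]
  ok <- !is.na(v) & !is.na(cv)
  if (model$kind == "categorical") {
    off <- model$offsets[as.character(cv[ok])]
    if (any(is.na(off)))
      stop("category not covered by fitted model: ",
           paste(unique(as.character(cv[ok])[is.na(off)]), collapse = ", "))
    v[ok] <- v[ok] - off
  } else {
    pred <- model$intercept + model$slope * cv[ok]
    v[ok] <- v[ok] - (pred - model$hc_mean)
  }
  records[[model$feature]] <- v
  records
}

#' Merge small racial-identity categories for adjustment
#'
#' Participants identifying as Black and as Other/more than one race form
#' small groups; they are combined into one category before the race
#' adjustment is fitted.
#'
#' @param race Character vector of racial identities.
#' @return Character vector with `"Black"` and `"Other"` mapped to
#'   `"Black/Other"`.
#' @export
merge_race_categories <- function(race) {
  out <- as.character(race)
  out[out %in% c("Black", "Other")] <- "Black/Other"
  out
}

#' Sequential HC-anchored covariate adjustment
#'
#' Walks the covariates in order. For each, tests its association with each
#' etymology feature at the whole-dataset level; if any association is
#' significant at `alpha`, ALL lexical features are adjusted for that
#' covariate using models fitted on HC records (median offsets for
#' categorical covariates, OLS residualization for continuous ones). Each
#' step is fitted on the current, already-adjusted values, and each
#' covariate is adjusted at most once. Race categories Black and Other are
#' merged before fitting. Antipsychotic use is tested within the CHR and ROP
#' cohorts separately for the audit trail but is never used as an adjustment
#' covariate (no HC uses antipsychotics, so no HC-anchored model exists).
#' Covariates with `subset_ok` (education, maternal education, IQ) are
#' tested and adjusted on the subset with non-missing values; other rows
#' pass through unchanged.
#'
#' @param records Participant data.frame with `cohort` and covariate columns
#'   plus the lexical feature columns.
#' @param lexical_features Columns to adjust.
#' @param etymology_features Columns whose associations gate the adjustment.
#' @param covariate_order data.frame as from [default_covariate_order()];
#'   covariates absent from `records` are skipped with an audit note.
#' @param alpha Gate significance level (uncorrected).
#' @param test_antipsychotic Also run the within-cohort antipsychotic tests.
#' @return List with `records` (adjusted), `audit` (one row per test), and
#'   `models` (fitted adjustment models, named by covariate).
#' @export
sequential_adjust <- function(records,
                              lexical_features = c("p_germanic",
                                                   "p_old_french",
                                                   "honore_R", "perplexity"),
                              etymology_features = c("p_germanic",
                                                     "p_old_french"),
                              covariate_order = default_covariate_order(),
                              alpha = 0.05,
                              test_antipsychotic = TRUE) {
  stopifnot(is.data.frame(records), "cohort" %in% names(records),
            all(lexical_features %in% names(records)),
            all(etymology_features %in% lexical_features))
  audit <- list()
  models <- list()
  log_row <- function(covariate, scope, feature, res, decision) {
    audit[[length(audit) + 1L]] <<- data.frame(
      covariate = covariate, scope = scope, feature = feature,
      method = res$method, statistic = res$statistic, p = res$p, n = res$n,
      decision = decision, stringsAsFactors = FALSE)
  }

  work <- records
  if ("race" %in% names(work)) work$race <- merge_race_categories(work$race)

  for (i in seq_len(nrow(covariate_order))) {
    cv <- covariate_order$covariate[i]
    kind <- covariate_order$kind[i]
    if (!cv %in% names(work)) next
    if (all(is.na(work[[cv]]))) next
    res_list <- lapply(etymology_features, function(f)
      tryCatch(test_association(work[[f]], work[[cv]], kind),
               error = function(e) NULL))
    if (any(vapply(res_list, is.null, logical(1)))) {
      log_row(cv, "whole_dataset", NA_character_,
              list(method = kind, statistic = NA_real_, p = NA_real_,
                   n = sum(!is.na(work[[cv]]))), "untestable")
      next
    }
    associated <- any(vapply(res_list, function(r) r$p < alpha, logical(1)))
    decision <- if (associated) "adjust" else "no_adjust"
    for (j in seq_along(etymology_features))
      log_row(cv, "whole_dataset", etymology_features[j], res_list[[j]],
              decision)
    if (associated) {
      fitter <- if (kind == "categorical") fit_categorical_adjustment
                else fit_continuous_adjustment
      for (f in lexical_features) {
        m <- fitter(work, f, cv)
        work <- apply_adjustment(m, work)
        models[[paste(cv, f, sep = ".")]] <- m
      }
    }
  }

  if (test_antipsychotic && "antipsychotic" %in% names(records)) {
    for (coh in intersect(c("CHR", "ROP"), unique(records$cohort))) {
      sub <- work[work$cohort == coh, , drop = FALSE]
      if (length(unique(stats::na.omit(sub$antipsychotic))) < 2L) next
      for (f in etymology_features) {
        res <- tryCatch(
          test_association(sub[[f]], sub$antipsychotic, "categorical"),
          error = function(e) NULL)
        if (!is.null(res))
          log_row("antipsychotic", paste0("within_", coh), f, res,
                  "never_adjusted")
      }
    }
  }

  list(records = work, audit = do.call(rbind, audit), models = models)
}
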