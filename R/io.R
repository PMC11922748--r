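#' Profile a directory (or set) of transcripts
#'
#' The transcript-level half of the pipeline: each transcript is read,
#' participant speech isolated, normalized, lemmatized and tagged, and its
#' lexical profile computed (etymology proportions, Honoré's statistic,
#' unigram perplexity). Unreadable or unanalyzable transcripts are skipped
#' with a logged error; the result records how many were skipped.
#'
#' @param transcripts Directory containing `.txt` transcripts, or a
#'   character vector of file paths.
#' @param lexicon An `etymology_lexicon` or a path readable by
#'   [read_lexicon()].
#' @param freq_table A `frequency_table` or a path readable by
#'   [load_frequency_table()].
#' @param tagger Tagger function (see [lookup_tagger()]), or the path of a
#'   TSV lookup table with columns `surface`, `lemma`, `upos`.
#' @param apostrophe,oov,log_base,hapax_correction Passed through to the
#'   preprocessing and metric functions.
#' @return data.frame of per-transcript profiles, with attributes `skipped`
#'   (character vector of failed paths) and `errors` (their messages).
#' @export
run_profile <- function(transcripts, lexicon, freq_table,
                        tagger = default_tagger(),
                        apostrophe = "strip", oov = "skip",
                        log_base = exp(1), hapax_correction = FALSE) {
  if (length(transcripts) == 1L && dir.exists(transcripts))
    transcripts <- sort(list.files(transcripts, pattern = "\\.txt$",
                                   full.names = TRUE))
  if (length(transcripts) == 0L) stop("no inputs: no transcripts found")
  if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
  if (is.character(freq_table)) freq_table <- load_frequency_table(freq_table)
  if (is.character(tagger))
    tagger <- lookup_tagger(utils::read.delim(tagger, quote = "",
                                              stringsAsFactors = FALSE))
  rows <- list()
  skipped <- character(0)
  errors <- character(0)
  for (path in transcripts) {
    res <- tryCatch({
      t <- read_transcript(path)
      pp <- preprocess_transcript(t, tagger, apostrophe)
      lexical_profile(pp$tokens, lexicon, freq_table,
                      transcript_id = t$transcript_id,
                      content = pp$content, oov = oov, log_base = log_base,
                      hapax_correction = hapax_correction)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", path, ": ", conditionMessage(res))
      skipped <- c(skipped, path)
      errors <- c(errors, conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) stop("no transcripts could be profiled")
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  attr(out, "errors") <- errors
  out
}

#' Write per-transcript profiles as CSV
#'
#' Proportions are printed to 6 decimals and statistics to 4; a header
#' comment carries the tool version and a hash of the content.
#'
#' @param profiles data.frame from [run_profile()].
#' @param path Output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  df <- profiles
  for (col in c("p_germanic", "p_old_french"))
    if (col %in% names(df)) df[[col]] <- sprintf("%.6f", df[[col]])
  for (col in c("honore_R", "perplexity", "mean_log_prob"))
    if (col %in% names(df)) df[[col]] <- sprintf("%.4f", df[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  payload <- utils::capture.output(
    utils::write.csv(df, row.names = FALSE))
  writeLines(paste0("# etymolex ",
                    as.character(utils::packageVersion("etymolex")),
                    " content-hash ",
                    content_hash(paste(payload, collapse = "\n"))), con)
  writeLines(payload, con)
  invisible(path)
}

# small stable polynomial content hash; avoids a digest dependency
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Compare cohorts: adjustment plus inferential layer
#'
#' The cohort-level half of the pipeline. Joins per-transcript profiles to
#' participant metadata, runs the sequential HC-anchored covariate
#' adjustment, then the inferential layer: one-way ANOVA with pairwise
#' pooled t tests per lexical feature, the Pearson correlation matrix of the
#' adjusted features, standardized multiple regressions for each etymology
#' proportion (on unadjusted outcomes, with cohort, lexical and demographic
#' predictors), and Spearman correlations with functioning scores in the
#' combined clinical cohort.
#'
#' @param profiles data.frame from [run_profile()] or [cohort_profiles()].
#' @param metadata Participant metadata data.frame (or CSV path) with
#'   `participant_id`, `transcript_id`, `cohort` and covariate columns.
#' @param site Optional site label: restrict the whole analysis to one
#'   recruitment site (the adjustment is refitted within the site).
#' @param alpha Gate level for the covariate-adjustment step.
#' @param family_k Number of tests in the Bonferroni family.
#' @param lexical_features,etymology_features Passed to
#'   [sequential_adjust()].
#' @return List with `data` (joined, adjusted), `audit`, `comparisons`
#'   (per-feature `group_comparison`), `correlations` (Pearson matrix),
#'   `regressions` (per-etymology `regression_report`), `clinical`
#'   (Spearman table), `bonferroni_alpha`, `orphans`.
#' @export
run_compare <- function(profiles, metadata, site = NULL, alpha = 0.05,
                        family_k = 20,
                        lexical_features = c("p_germanic", "p_old_french",
                                             "honore_R", "perplexity"),
                        etymology_features = c("p_germanic",
                                               "p_old_french")) {
  if (is.character(metadata))
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  required <- c("participant_id", "transcript_id", "cohort")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("missing required metadata columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(metadata$cohort), c("HC", "CHR", "ROP"))
  if (length(bad))
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  orphans <- list(
    profiles = setdiff(profiles$transcript_id, metadata$transcript_id),
    metadata = setdiff(metadata$transcript_id, profiles$transcript_id))
  if (length(orphans$profiles) || length(orphans$metadata))
    message("unmatched transcripts: ", length(orphans$profiles),
            " profiled-only, ", length(orphans$metadata), " metadata-only")
  dat <- merge(metadata, profiles, by = "transcript_id")
  if (!is.null(site)) {
    if (!site %in% dat$site) stop("no participants at site '", site, "'")
    dat <- dat[dat$site == site, , drop = FALSE]
  }

  raw <- dat
  adj <- sequential_adjust(dat, lexical_features = lexical_features,
                           etymology_features = etymology_features,
                           alpha = alpha)
  dat <- adj$records

  comparisons <- lapply(lexical_features, function(f)
    anova_and_pairwise(dat[[f]], dat$cohort, feature = f))
  names(comparisons) <- lexical_features

  correlations <- correlation_matrix(dat[, lexical_features, drop = FALSE])

  reg_predictors <- intersect(
    c("cohort", "honore_R", "perplexity", "education", "age", "sex",
      "site", "race"),
    names(raw))
  if (!is.null(site)) reg_predictors <- setdiff(reg_predictors, "site")
  regressions <- lapply(etymology_features, function(f) {
    preds <- setdiff(reg_predictors, f)
    tryCatch(
      standardized_regression(raw, f, preds,
                              references = c(cohort = "HC",
                                             site = "Melbourne",
                                             race = "Asian", sex = "male")),
      error = function(e) e)
  })
  names(regressions) <- etymology_features

  clinical <- if (all(c("gf_role", "gf_social") %in% names(dat)))
    clinical_correlations(dat, etymology_features, k = family_k,
                          alpha = alpha)
  else NULL

  list(data = dat, audit = adj$audit, comparisons = comparisons,
       correlations = correlations, regressions = regressions,
       clinical = clinical,
       bonferroni_alpha = bonferroni_alpha(alpha, family_k),
       orphans = orphans)
}

#' Write comparison results as tidy CSV, audit JSON and a text report
#'
#' @param results List from [run_compare()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_compare <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (f in names(results$comparisons)) {
    gc <- results$comparisons[[f]]
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, test = "anova", group1 = NA, group2 = NA,
      statistic = gc$anova$F, df = paste(gc$anova$df1, gc$anova$df2,
                                         sep = ","),
      p = gc$anova$p, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(gc$pairwise)))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, test = "pairwise_t",
        group1 = gc$pairwise$group1[i], group2 = gc$pairwise$group2[i],
        statistic = gc$pairwise$t[i],
        df = as.character(gc$pairwise$df[i]),
        p = gc$pairwise$p[i], stringsAsFactors = FALSE)
  }
  tidy <- do.call(rbind, rows)
  tidy$statistic <- round(tidy$statistic, 4)
  tidy$p <- signif(tidy$p, 4)
  utils::write.csv(tidy, file.path(dir, "group_tests.csv"),
                   row.names = FALSE)
  if (!is.null(results$audit))
    jsonlite::write_json(results$audit, file.path(dir, "audit.json"),
                         digits = NA, auto_unbox = TRUE)
  rep_lines <- c("etymolex comparison report", "",
                 sprintf("Bonferroni-corrected alpha: %.4g",
                         results$bonferroni_alpha), "")
  for (f in names(results$comparisons)) {
    gc <- results$comparisons[[f]]
    rep_lines <- c(rep_lines, sprintf(
      "%s: F(%d, %d) = %.3f, p = %.4g", f, gc$anova$df1, gc$anova$df2,
      gc$anova$F, gc$anova$p))
  }
  writeLines(rep_lines, file.path(dir, "report.txt"))
  invisible(dir)
}
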