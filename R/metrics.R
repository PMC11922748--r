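#' Honoré's statistic of lexical diversity
#'
#' R = 100 * log(N) / (1 - V1/V), where N is the total token count of the
#' whole lemmatized text, V the number of distinct lemmas and V1 the number
#' of hapax legomena (lemmas occurring exactly once). Larger R means greater
#' vocabulary breadth for the text length. The statistic is computed on the
#' WHOLE lemmatized text, not the content-word subset.
#'
#' When every type is a hapax (V1 = V) the denominator vanishes; by default
#' this raises an error rather than returning infinity. With
#' `hapax_correction = TRUE` the common correction V1 -> V - 0.5 is applied
#' in that case.
#'
#' @param lemmas Character vector: the lemma sequence of the whole text.
#' @param log_base Base of the logarithm; natural log by default (the base
#'   used in the statistic's original definition).
#' @param hapax_correction Apply the V1 -> V - 0.5 correction when V1 = V.
#' @return The statistic (a single number).
#' @export
honore_statistic <- function(lemmas, log_base = exp(1),
                             hapax_correction = FALSE) {
  if (length(lemmas) == 0L) stop("empty text: Honoré's statistic undefined")
  n <- length(lemmas)
  counts <- table(lemmas)
  v <- length(counts)
  v1 <- sum(counts == 1L)
  if (v1 == v) {
    if (!hapax_correction)
      stop("every type is a hapax (V1 = V): Honoré's statistic undefined; ",
           "set hapax_correction = TRUE to apply the V1 -> V - 0.5 correction")
    v1 <- v - 0.5
  }
  100 * log(n, base = log_base) / (1 - v1 / v)
}

#' Construct a unigram frequency table
#'
#' @param counts Named numeric vector of nonnegative corpus counts (names
#'   are words).
#' @param total Total corpus size; defaults to `sum(counts)`. Unary word
#'   probabilities are count/total.
#' @return A `frequency_table` object.
#' @export
frequency_table <- function(counts, total = sum(counts)) {
  if (length(counts) == 0L) stop("empty frequency table")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by word")
  if (anyDuplicated(names(counts)))
    stop("duplicate words in frequency table")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative")
  if (total < max(counts)) stop("total smaller than the largest count")
  structure(list(counts = counts, total = as.numeric(total)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> ", length(x$counts), " words, total ",
      format(x$total, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Load a unigram frequency table from TSV
#'
#' Expected format: two tab-separated columns, word and count, no header
#' row. An optional leading comment line `#total N` overrides the corpus
#' total (useful when the table is a truncated slice of a larger corpus).
#'
#' @param path TSV file path.
#' @return A `frequency_table`.
#' @export
load_frequency_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty frequency table file: ", path)
  total_override <- NULL
  header <- grepl("^#", lines)
  tot_line <- grep("^#total\\s+", lines)
  if (length(tot_line))
    total_override <- as.numeric(sub("^#total\\s+", "", lines[tot_line[1]]))
  body_idx <- which(!header & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("no data rows in frequency table: ", path)
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    stop("malformed frequency table row at line ",
         body_idx[which(bad)[1]], " of ", path)
  words <- vapply(parts, `[[`, character(1), 1L)
  count_str <- vapply(parts, `[[`, character(1), 2L)
  counts <- suppressWarnings(as.numeric(count_str))
  nonint <- is.na(counts) | counts != floor(counts) | counts < 0
  if (any(nonint))
    stop("non-integer or negative count at line ",
         body_idx[which(nonint)[1]], " of ", path)
  dup <- duplicated(words)
  if (any(dup))
    stop("duplicate word '", words[which(dup)[1]], "' at line ",
         body_idx[which(dup)[1]], " of ", path)
  names(counts) <- words
  if (is.null(total_override)) frequency_table(counts)
  else frequency_table(counts, total = total_override)
}

#' Write a frequency table to TSV
#'
#' @param ft A `frequency_table`.
#' @param path Output path. The corpus total is written as a `#total` header.
#' @export
write_frequency_table <- function(ft, path) {
  stopifnot(inherits(ft, "frequency_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#total ", format(ft$total, scientific = FALSE)), con)
  writeLines(paste(names(ft$counts),
                   format(ft$counts, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' First-order (unigram) transcript perplexity
#'
#' Treats the probability of a transcript as the product of each content
#' lemma's unary probability w_i = count_i / total in the reference corpus.
#' The transcript score is the mean log probability
#' m = (1/n) * sum(log(w_i)) over scored tokens and the perplexity
#' Pi = exp(-m) (base matching `log_base`), so rarer vocabulary gives larger
#' perplexity; both are returned. Only content tokens (nouns, verbs,
#' adjectives, adverbs) are scored.
#'
#' Out-of-vocabulary handling: `"skip"` (default) excludes unlisted or
#' zero-count tokens and counts them in `oov_count`; `"floor"` scores them
#' at probability 1/total.
#'
#' @param content_tokens `token_records` restricted to content words.
#' @param ft A `frequency_table`.
#' @param oov Out-of-vocabulary policy, `"skip"` or `"floor"`.
#' @param log_base Logarithm base (natural log by default).
#' @return List with `perplexity`, `mean_log_prob`, `n_scored`, `oov_count`.
#' @export
transcript_perplexity <- function(content_tokens, ft,
                                  oov = c("skip", "floor"),
                                  log_base = exp(1)) {
  oov <- match.arg(oov)
  stopifnot(inherits(ft, "frequency_table"),
            is.data.frame(content_tokens), "lemma" %in% names(content_tokens))
  if (ft$total <= 0) stop("frequency table total must be positive")
  lemmas <- content_tokens$lemma
  if (length(lemmas) == 0L) stop("no content tokens to score")
  cnt <- ft$counts[lemmas]
  known <- !is.na(cnt) & cnt > 0
  w <- numeric(length(lemmas))
  w[known] <- cnt[known] / ft$total
  if (oov == "floor") {
    w[!known] <- 1 / ft$total
    scored <- rep(TRUE, length(lemmas))
  } else {
    scored <- known
  }
  n_scored <- sum(scored)
  if (n_scored == 0L)
    stop("no scorable tokens (all out of vocabulary under the skip policy)")
  mean_log_prob <- mean(log(w[scored], base = log_base))
  list(perplexity = log_base^(-mean_log_prob),
       mean_log_prob = mean_log_prob,
       n_scored = n_scored,
       oov_count = length(lemmas) - sum(known))
}

#' Per-transcript lexical profile
#'
#' Runs the three transcript-level measures — etymology proportions on
#' content tokens, Honoré's statistic on the whole lemma sequence, unigram
#' perplexity on content tokens — and returns them as a one-row data.frame
#' suitable for row-binding across transcripts.
#'
#' @param tokens All `token_records` of the transcript.
#' @param lex An `etymology_lexicon`.
#' @param ft A `frequency_table`.
#' @param transcript_id Identifier copied into the output row.
#' @param content Precomputed content subsequence; defaults to
#'   [select_content_tokens()] of `tokens`.
#' @param oov,log_base,hapax_correction Passed through to the metric
#'   functions.
#' @return One-row data.frame with columns `transcript_id`, `n_tokens`,
#'   `n_content`, `p_germanic`, `p_old_french`, `n_both`, `n_neither`,
#'   `n_unknown`, `honore_R`, `perplexity`, `mean_log_prob`, `n_scored`,
#'   `oov_count`.
#' @export
lexical_profile <- function(tokens, lex, ft, transcript_id = NA_character_,
                            content = select_content_tokens(tokens),
                            oov = "skip", log_base = exp(1),
                            hapax_correction = FALSE) {
  prop <- compute_proportions(content, lex)
  hon <- honore_statistic(tokens$lemma, log_base = log_base,
                          hapax_correction = hapax_correction)
  ppl <- transcript_perplexity(content, ft, oov = oov, log_base = log_base)
  data.frame(transcript_id = as.character(transcript_id),
             n_tokens = nrow(tokens),
             n_content = prop$n_content,
             p_germanic = prop$p_germanic,
             p_old_french = prop$p_old_french,
             n_both = prop$n_both,
             n_neither = prop$n_neither,
             n_unknown = prop$n_unknown,
             honore_R = hon,
             perplexity = ppl$perplexity,
             mean_log_prob = ppl$mean_log_prob,
             n_scored = ppl$n_scored,
             oov_count = ppl$oov_count,
             stringsAsFactors = FALSE)
}
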