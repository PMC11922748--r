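#' Default origin-language label groupings
#'
#' The lexicon records origin languages as free-text labels; these defaults
#' define which labels count as Germanic and which as Old French. The
#' groupings are a documented choice (standard Germanic ancestry of English
#' plus the Norman French entry route) and fully configurable.
#'
#' @return Character vector of labels.
#' @export
default_germanic_labels <- function() {
  c("Old English", "Proto-Germanic", "Proto-West Germanic", "Old Norse",
    "Middle English", "Old High German", "Middle Dutch", "Middle Low German")
}

#' @rdname default_germanic_labels
#' @export
default_old_french_labels <- function() {
  c("Old French", "Anglo-Norman")
}

#' Default etymological relation types accepted when compiling a lexicon
#'
#' Edge lists extracted from collaborative etymology databases carry typed
#' relations; only genuine ancestry/borrowing relations contribute origins.
#' "cognate with" and similar lateral relations are excluded.
#'
#' @return Character vector of relation types.
#' @export
default_accepted_relations <- function() {
  c("inherited from", "derived from", "borrowed from")
}

#' Construct an etymology lexicon
#'
#' @param entries Named list mapping lowercase lemma to a character vector of
#'   origin-language labels.
#' @param germanic_labels,old_french_labels Label groupings; must be
#'   disjoint.
#' @return An `etymology_lexicon` object.
#' @export
etymology_lexicon <- function(entries,
                              germanic_labels = default_germanic_labels(),
                              old_french_labels = default_old_french_labels()) {
  stopifnot(is.list(entries))
  if (length(entries) && is.null(names(entries)))
    stop("entries must be a named list (lemma -> origin labels)")
  if (length(intersect(germanic_labels, old_french_labels)))
    stop("germanic and old-french label sets must be disjoint")
  names(entries) <- tolower(names(entries))
  entries <- lapply(entries, function(x) unique(as.character(x)))
  # precompute per-lemma origin class once; classify_lemma is then a lookup
  class_map <- vapply(entries, function(origins) {
    g <- any(origins %in% germanic_labels)
    f <- any(origins %in% old_french_labels)
    if (g && f) "BOTH"
    else if (g) "GERMANIC_ONLY"
    else if (f) "OLD_FRENCH_ONLY"
    else "NEITHER"
  }, character(1))
  structure(list(entries = entries,
                 germanic_labels = germanic_labels,
                 old_french_labels = old_french_labels,
                 class_map = class_map),
            class = "etymology_lexicon")
}

#' @export
print.etymology_lexicon <- function(x, ...) {
  cat("<etymology_lexicon> ", length(x$entries), " lemmas; ",
      length(x$germanic_labels), " Germanic labels, ",
      length(x$old_french_labels), " Old French labels\n", sep = "")
  invisible(x)
}

#' Compile a lexicon from an etymology edge list
#'
#' Takes tabulated (word, relation_type, origin_language) triples — the form
#' in which collaborative etymology databases are distributed — and keeps,
#' per word, the set of origin languages reachable through accepted relation
#' types. Words with no accepted edge are absent from the result (and will
#' classify as UNKNOWN). Origins are taken as listed: no transitive chasing
#' of etymological chains is attempted; resolving chains is the lexicon
#' builder's job upstream.
#'
#' @param edges data.frame with columns `word`, `relation_type`,
#'   `origin_language`.
#' @param accepted_relations Non-empty character vector of relation types to
#'   keep.
#' @param germanic_labels,old_french_labels Passed to [etymology_lexicon()].
#' @return An `etymology_lexicon`.
#' @export
compile_lexicon <- function(edges,
                            accepted_relations = default_accepted_relations(),
                            germanic_labels = default_germanic_labels(),
                            old_french_labels = default_old_french_labels()) {
  stopifnot(is.data.frame(edges),
            all(c("word", "relation_type", "origin_language") %in% names(edges)))
  if (length(accepted_relations) == 0L)
    stop("accepted_relations must be non-empty")
  word <- tolower(trimws(as.character(edges$word)))
  rel <- trimws(as.character(edges$relation_type))
  origin <- trimws(as.character(edges$origin_language))
  malformed <- is.na(word) | !nzchar(word) | is.na(rel) | !nzchar(rel) |
    is.na(origin) | !nzchar(origin)
  if (any(malformed))
    message("compile_lexicon: skipped ", sum(malformed), " malformed edge row(s)")
  keep <- !malformed & rel %in% accepted_relations
  entries <- lapply(split(origin[keep], word[keep]), unique)
  etymology_lexicon(entries, germanic_labels, old_french_labels)
}

#' Read a lexicon from a TSV file
#'
#' Two dialects are accepted: columns `lemma`, `origin_languages`
#' (semicolon-separated labels), or an edge list with columns `word`,
#' `relation_type`, `origin_language` which is passed through
#' [compile_lexicon()].
#'
#' @param path TSV file path.
#' @param ... Passed on to [etymology_lexicon()] or [compile_lexicon()].
#' @return An `etymology_lexicon`.
#' @export
read_lexicon <- function(path, ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (all(c("lemma", "origin_languages") %in% names(tab))) {
    entries <- lapply(strsplit(tab$origin_languages, ";", fixed = TRUE),
                      trimws)
    names(entries) <- tolower(tab$lemma)
    etymology_lexicon(entries, ...)
  } else if (all(c("word", "relation_type", "origin_language") %in% names(tab))) {
    compile_lexicon(tab, ...)
  } else {
    stop("unrecognized lexicon format: need lemma/origin_languages or ",
         "word/relation_type/origin_language columns")
  }
}

#' Write a lexicon to TSV (lemma / semicolon-joined origins)
#'
#' @param lex An `etymology_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "etymology_lexicon"))
  df <- data.frame(lemma = names(lex$entries),
                   origin_languages = vapply(lex$entries, paste,
                                             character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

origin_classes <- c("GERMANIC_ONLY", "OLD_FRENCH_ONLY", "BOTH", "NEITHER",
                    "UNKNOWN")

#' Classify lemmas by word origin
#'
#' A lemma is GERMANIC_ONLY if its origin set intersects the Germanic labels
#' but not the Old French labels; OLD_FRENCH_ONLY symmetrically; BOTH if it
#' intersects both (e.g. "talkative", Germanic stem with a French suffix);
#' NEITHER if it is in the lexicon but intersects neither (e.g. "karaoke");
#' UNKNOWN if the lexicon has no entry.
#'
#' @param lex An `etymology_lexicon`.
#' @param lemma Character vector of lowercase lemmas.
#' @return Character vector of origin classes, same length as `lemma`.
#' @export
classify_lemma <- function(lex, lemma) {
  stopifnot(inherits(lex, "etymology_lexicon"))
  cls <- unname(lex$class_map[lemma])
  cls[is.na(cls)] <- "UNKNOWN"
  cls
}

#' Compute per-transcript etymology proportions
#'
#' Counts every content-token occurrence (token-level, not type-level) and
#' reports the fraction of content tokens whose origin is exclusively
#' Germanic and exclusively Old French. The denominator is ALL content
#' tokens: tokens of mixed (BOTH), other (NEITHER) or unknown origin count
#' in the denominator but in neither numerator — the exclusivity rule
#' restricts the numerators, not the denominator. Set `per_type = TRUE` to
#' count unique lemmas instead of running tokens.
#'
#' @param content_tokens `token_records` restricted to content words.
#' @param lex An `etymology_lexicon`.
#' @param per_type Count each distinct lemma once instead of per token.
#' @return An `etymology_proportions` object (list of counts and the two
#'   proportions).
#' @export
compute_proportions <- function(content_tokens, lex, per_type = FALSE) {
  stopifnot(is.data.frame(content_tokens), "lemma" %in% names(content_tokens))
  lemmas <- content_tokens$lemma
  if (per_type) lemmas <- unique(lemmas)
  n <- length(lemmas)
  if (n == 0L) stop("no content tokens: etymology proportions undefined")
  cls <- classify_lemma(lex, lemmas)
  counts <- table(factor(cls, levels = origin_classes))
  out <- list(n_content = n,
              n_germanic = unname(counts[["GERMANIC_ONLY"]]),
              n_old_french = unname(counts[["OLD_FRENCH_ONLY"]]),
              n_both = unname(counts[["BOTH"]]),
              n_neither = unname(counts[["NEITHER"]]),
              n_unknown = unname(counts[["UNKNOWN"]]))
  out$p_germanic <- out$n_germanic / n
  out$p_old_french <- out$n_old_french / n
  class(out) <- "etymology_proportions"
  out
}

#' @export
print.etymology_proportions <- function(x, ...) {
  cat(sprintf(
    "<etymology_proportions> n=%d  Germanic %.3f  Old French %.3f  (both %d, neither %d, unknown %d)\n",
    x$n_content, x$p_germanic, x$p_old_french, x$n_both, x$n_neither,
    x$n_unknown))
  invisible(x)
}
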