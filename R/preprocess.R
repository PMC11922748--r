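#' Read an interview transcript
#'
#' Reads a plain-text transcript file. If lines begin with a speaker label
#' ("Interviewer:" / "Participant:", case-insensitive, configurable via
#' `label_map`), the file is parsed as a labelled dialogue; otherwise the
#' whole file is treated as a single participant monologue, so the tool
#' works on unlabelled text.
#'
#' @param path Path to a UTF-8 text file.
#' @param transcript_id Identifier for the transcript; defaults to the file
#'   name without extension.
#' @param label_map Named character vector mapping lowercase labels found in
#'   the file to speaker roles `"interviewer"` / `"participant"`.
#' @return A `raw_transcript` object: a list with `transcript_id` and an
#'   `utterances` data.frame (columns `speaker`, `text`).
#' @export
read_transcript <- function(path,
                            transcript_id = sub("\\.[^.]*$", "", basename(path)),
                            label_map = c(interviewer = "interviewer",
                                          participant = "participant")) {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  label_re <- "^\\s*([A-Za-z ]+?)\\s*:\\s*(.*)$"
  labelled <- grepl(label_re, lines) &
    tolower(sub(label_re, "\\1", lines)) %in% names(label_map)
  if (any(labelled)) {
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    labelled <- labelled[keep]
    speaker <- character(length(lines))
    text <- character(length(lines))
    current <- NA_character_
    for (i in seq_along(lines)) {
      if (labelled[i]) {
        current <- unname(label_map[[tolower(sub(label_re, "\\1", lines[i]))]])
        text[i] <- sub(label_re, "\\2", lines[i])
      } else {
        text[i] <- lines[i]
      }
      speaker[i] <- current
    }
    ok <- !is.na(speaker) & nzchar(trimws(text))
    utter <- data.frame(speaker = speaker[ok], text = trimws(text[ok]),
                        stringsAsFactors = FALSE)
  } else {
    utter <- data.frame(speaker = "participant",
                        text = paste(trimws(lines[nzchar(trimws(lines))]),
                                     collapse = " "),
                        stringsAsFactors = FALSE)
  }
  raw_transcript(transcript_id, utter)
}

#' Construct a raw transcript object
#'
#' @param transcript_id Opaque identifier string.
#' @param utterances data.frame with columns `speaker` (one of
#'   `"interviewer"`, `"participant"`) and `text`.
#' @return A `raw_transcript` object.
#' @export
raw_transcript <- function(transcript_id, utterances) {
  stopifnot(is.data.frame(utterances),
            all(c("speaker", "text") %in% names(utterances)))
  if (nrow(utterances) < 1L)
    stop("transcript '", transcript_id, "' has no utterances")
  bad <- setdiff(unique(utterances$speaker), c("interviewer", "participant"))
  if (length(bad))
    stop("unknown speaker role(s): ", paste(bad, collapse = ", "))
  structure(list(transcript_id = as.character(transcript_id),
                 utterances = utterances),
            class = "raw_transcript")
}

#' @export
print.raw_transcript <- function(x, ...) {
  n_part <- sum(x$utterances$speaker == "participant")
  cat("<raw_transcript> ", x$transcript_id, ": ",
      nrow(x$utterances), " utterances (", n_part, " participant)\n", sep = "")
  invisible(x)
}

#' Isolate participant speech from a transcript
#'
#' Concatenates the participant-role utterances in order, joined by single
#' spaces; interviewer text is dropped.
#'
#' @param t A `raw_transcript`.
#' @return A single string of participant speech.
#' @export
isolate_participant_speech <- function(t) {
  stopifnot(inherits(t, "raw_transcript"))
  part <- t$utterances$text[t$utterances$speaker == "participant"]
  if (length(part) == 0L)
    stop("empty participant speech in transcript '", t$transcript_id, "'")
  paste(part, collapse = " ")
}

#' Normalize transcript text
#'
#' Lowercases, removes punctuation and other non-alphanumeric symbols, and
#' collapses whitespace. Word-internal apostrophes are by default stripped so
#' contractions collapse ("don't" -> "dont"); with
#' `apostrophe = "split"` they become token boundaries instead. Hyphenated
#' compounds always split at the hyphen (a hyphen is punctuation). The
#' operation is idempotent.
#'
#' @param text Character vector of UTF-8 text.
#' @param apostrophe Either `"strip"` (default) or `"split"`.
#' @return Normalized character vector of the same length.
#' @export
normalize_text <- function(text, apostrophe = c("strip", "split")) {
  apostrophe <- match.arg(apostrophe)
  out <- tolower(text)
  apo <- "['’]"
  out <- gsub(apo, if (apostrophe == "strip") "" else " ", out)
  out <- gsub("[^[:alnum:]]+", " ", out)
  trimws(gsub("\\s+", " ", out))
}

#' Build a lookup-table tagger
#'
#' The lemmatizer contract is a plain function: it takes a character vector
#' of normalized tokens and returns a data.frame with columns `lemma` and
#' `upos` (one row per token, `upos` in NOUN/VERB/ADJ/ADV/OTHER). This
#' constructor builds a deterministic tagger from a lookup table, falling
#' back on simple suffix rules for tokens not in the table. Any production
#' adapter wrapping a statistical tagger satisfies the same contract.
#'
#' @param table data.frame with columns `surface`, `lemma`, `upos`. Tokens
#'   absent from the table fall through to `fallback`.
#' @param fallback Function applied to unknown tokens; the default applies
#'   suffix heuristics (-ly adverb, -ing/-ed verb, plural -s noun) and
#'   otherwise keeps the token with tag OTHER.
#' @return A tagger function.
#' @export
lookup_tagger <- function(table, fallback = suffix_rule_tagger) {
  stopifnot(all(c("surface", "lemma", "upos") %in% names(table)))
  surface <- tolower(table$surface)
  if (anyDuplicated(surface))
    stop("duplicate surface forms in tagger table")
  lemma <- tolower(table$lemma)
  upos <- toupper(table$upos)
  upos[!upos %in% c("NOUN", "VERB", "ADJ", "ADV")] <- "OTHER"
  function(tokens) {
    i <- match(tokens, surface)
    hit <- !is.na(i)
    out <- data.frame(lemma = tokens, upos = "OTHER",
                      stringsAsFactors = FALSE)
    out$lemma[hit] <- lemma[i[hit]]
    out$upos[hit] <- upos[i[hit]]
    if (any(!hit)) out[!hit, ] <- fallback(tokens[!hit])
    out
  }
}

#' Suffix-rule fallback tagger
#'
#' Deterministic heuristics for tokens missing from a lookup table: `-ly`
#' forms are adverbs (lemma kept), `-ing`/`-ed` forms are verbs (suffix
#' stripped, final consonant de-doubled), plural `-s` nouns are singularized.
#' Everything else is kept verbatim with tag OTHER. Intentionally crude: it
#' exists so the pipeline degrades predictably, not to rival a real
#' lemmatizer.
#'
#' @param tokens Character vector of normalized tokens.
#' @return data.frame with columns `lemma`, `upos`.
#' @export
suffix_rule_tagger <- function(tokens) {
  lemma <- tokens
  upos <- rep("OTHER", length(tokens))
  strip_double <- function(x) sub("([a-z])\\1$", "\\1", x)

  i <- grepl("[a-z]ly$", tokens) & nchar(tokens) > 4
  upos[i] <- "ADV"

  i <- grepl("[a-z]ing$", tokens) & nchar(tokens) > 5 & upos == "OTHER"
  lemma[i] <- strip_double(sub("ing$", "", tokens[i]))
  upos[i] <- "VERB"

  i <- grepl("[a-z]ed$", tokens) & nchar(tokens) > 4 & upos == "OTHER"
  lemma[i] <- strip_double(sub("ed$", "", tokens[i]))
  upos[i] <- "VERB"

  i <- grepl("[a-z]s$", tokens) & !grepl("ss$", tokens) &
    nchar(tokens) > 3 & upos == "OTHER"
  lemma[i] <- sub("s$", "", tokens[i])
  upos[i] <- "NOUN"

  data.frame(lemma = lemma, upos = upos, stringsAsFactors = FALSE)
}

#' Bundled deterministic tagger
#'
#' A lookup tagger over a small built-in English table (function words plus
#' common inflections, e.g. "is"/"am" -> "be") with the suffix-rule
#' fallback. Adequate for fixtures and the synthetic generator's vocabulary,
#' where surface forms are their own lemmas.
#'
#' @return A tagger function (see [lookup_tagger()]).
#' @export
default_tagger <- function() {
  path <- system.file("extdata", "tagger_table.tsv", package = "etymolex")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
  lookup_tagger(tab)
}

#' Lemmatize and POS-tag normalized text
#'
#' Tokenizes on whitespace and applies the tagger to obtain one token record
#' per token: surface form, lowercase lemma, universal POS class
#' (NOUN/VERB/ADJ/ADV/OTHER) and 0-based position. If the tagger fails on a
#' token (error, or NA/empty lemma), the token is kept with its surface form
#' as lemma and tag OTHER, with a warning.
#'
#' @param text A normalized string (see [normalize_text()]).
#' @param tagger A tagger function satisfying the lemmatizer contract.
#' @return A `token_records` data.frame with columns `index`, `surface`,
#'   `lemma`, `upos`.
#' @export
lemmatize_and_tag <- function(text, tagger = default_tagger()) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    return(empty_token_records())
  tagged <- tryCatch(tagger(tokens), error = function(e) NULL)
  bad_shape <- is.null(tagged) || !is.data.frame(tagged) ||
    nrow(tagged) != length(tokens) ||
    !all(c("lemma", "upos") %in% names(tagged))
  if (bad_shape) {
    warning("tagger failed; keeping surface forms with tag OTHER")
    tagged <- data.frame(lemma = tokens, upos = "OTHER",
                         stringsAsFactors = FALSE)
  }
  lemma <- tolower(as.character(tagged$lemma))
  upos <- toupper(as.character(tagged$upos))
  failed <- is.na(lemma) | !nzchar(lemma)
  if (any(failed)) {
    warning(sum(failed), " token(s) had no tagger output; kept as OTHER")
    lemma[failed] <- tokens[failed]
    upos[failed] <- "OTHER"
  }
  upos[!upos %in% c("NOUN", "VERB", "ADJ", "ADV")] <- "OTHER"
  out <- data.frame(index = seq_along(tokens) - 1L, surface = tokens,
                    lemma = lemma, upos = upos, stringsAsFactors = FALSE)
  class(out) <- c("token_records", "data.frame")
  out
}

empty_token_records <- function() {
  out <- data.frame(index = integer(0), surface = character(0),
                    lemma = character(0), upos = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("token_records", "data.frame")
  out
}

#' Select content-word tokens
#'
#' Restricts a token stream to the content-word classes carrying
#' Germanic/Old-French synonym choices: nouns, verbs, adjectives and
#' adverbs. Order is preserved; the result may be empty. Proper nouns are
#' tagged OTHER upstream and therefore excluded.
#'
#' @param tokens A `token_records` data.frame from [lemmatize_and_tag()].
#' @return The content-word subsequence, same columns.
#' @export
select_content_tokens <- function(tokens) {
  stopifnot(is.data.frame(tokens), "upos" %in% names(tokens))
  out <- tokens[tokens$upos %in% c("NOUN", "VERB", "ADJ", "ADV"), ,
                drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("token_records", "data.frame")
  out
}

#' Full preprocessing of one transcript
#'
#' Convenience wrapper running participant isolation, normalization,
#' lemmatization/tagging and content-word selection.
#'
#' @param t A `raw_transcript`.
#' @param tagger Tagger function.
#' @param apostrophe Apostrophe policy for [normalize_text()].
#' @return List with `tokens` (all token records) and `content` (the
#'   content-word subsequence).
#' @export
preprocess_transcript <- function(t, tagger = default_tagger(),
                                  apostrophe = "strip") {
  text <- normalize_text(isolate_participant_speech(t), apostrophe)
  tokens <- lemmatize_and_tag(text, tagger)
  list(tokens = tokens, content = select_content_tokens(tokens))
}
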