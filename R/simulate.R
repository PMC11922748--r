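#' Specification for the synthetic-cohort generator
#'
#' Bundles every knob of the generator with defaults set to the study
#' conditions the package targets: three cohorts (healthy comparison HC,
#' clinical high risk CHR, recent-onset psychosis ROP) with the cohort sizes,
#' etymology mixtures, demographics and clinical-score distributions of a
#' multisite psychosis speech study, a Zipfian synthetic vocabulary, and a
#' rank coupling between Old-French word use and role functioning in the
#' clinical cohorts.
#'
#' @param vocab_size Number of distinct words in the synthetic vocabulary.
#' @param zipf_exponent Exponent s of the rank-frequency law count ~ rank^-s.
#' @param pos_dist Named probabilities over token POS classes
#'   (NOUN/VERB/ADJ/ADV/OTHER); the OTHER mass models function words.
#' @param type_mixture Named probabilities over origin classes at the
#'   vocabulary-type level for content words.
#' @param rest_split How the non-(exclusively Germanic/Old French) token
#'   mass of each participant splits over BOTH/NEITHER/UNKNOWN.
#' @param cohorts data.frame of per-cohort parameters: sizes, target token
#'   mixtures, demographic means/SDs, antipsychotic rates, functioning and
#'   symptom score distributions.
#' @param tokens_mean,tokens_sd,tokens_min Tokens per transcript
#'   (Gaussian, truncated below at `tokens_min`); about 1500 tokens emulates
#'   a 30-minute open-ended interview.
#' @param between_sd_germanic,between_sd_old_french Between-participant SDs
#'   of the true mixtures, on the proportion scale.
#' @param sex_effect,age_slope,site_offsets,education_slope,race_offsets,
#'   maternal_slope,iq_slope Additive covariate effects on the Germanic
#'   mixture logit (mirrored with opposite sign on the Old-French logit).
#'   Units: logits (per year for the slopes).
#' @param site_probs Site membership probabilities.
#' @param iq_present Fraction of participants with an IQ score.
#' @param clinical_rho Target Spearman correlation between the Old-French
#'   proportion and role functioning within the clinical cohorts, induced
#'   through a Gaussian copula.
#' @return A `generator_spec` object (a validated list).
#' @export
generator_spec <- function(
    vocab_size = 5000,
    zipf_exponent = 1.0,
    pos_dist = c(NOUN = 0.20, VERB = 0.18, ADJ = 0.09, ADV = 0.08,
                 OTHER = 0.45),
    type_mixture = c(GERMANIC_ONLY = 0.50, OLD_FRENCH_ONLY = 0.22,
                     BOTH = 0.10, NEITHER = 0.12, UNKNOWN = 0.06),
    rest_split = c(BOTH = 0.35, NEITHER = 0.40, UNKNOWN = 0.25),
    cohorts = default_cohort_table(),
    tokens_mean = 1500, tokens_sd = 300, tokens_min = 200,
    between_sd_germanic = 0.032,
    between_sd_old_french = 0.026,
    sex_effect = -0.03,
    age_slope = -0.005,
    site_offsets = c(NewYork = 0.03, Melbourne = 0, Toronto = 0.01),
    education_slope = -0.02,
    race_offsets = c(Asian = 0, Black = 0.02, White = 0.01, Other = 0.02),
    maternal_slope = 0,
    iq_slope = -0.003,
    site_probs = c(NewYork = 0.45, Melbourne = 0.35, Toronto = 0.20),
    iq_present = 0.66,
    clinical_rho = 0.26) {
  if (vocab_size < 100) stop("vocabulary size must be at least 100")
  stopifnot(abs(sum(pos_dist) - 1) < 1e-8,
            abs(sum(type_mixture) - 1) < 1e-8,
            abs(sum(rest_split) - 1) < 1e-8)
  if (any(cohorts$p_germanic + cohorts$p_old_french > 1))
    stop("infeasible mixture: p_germanic + p_old_french > 1")
  if (any(cohorts$p_germanic < 0) || any(cohorts$p_old_french < 0))
    stop("mixtures must lie in [0, 1]")
  spec <- list(vocab_size = vocab_size, zipf_exponent = zipf_exponent,
               pos_dist = pos_dist, type_mixture = type_mixture,
               rest_split = rest_split, cohorts = cohorts,
               tokens_mean = tokens_mean, tokens_sd = tokens_sd,
               tokens_min = tokens_min,
               between_sd_germanic = between_sd_germanic,
               between_sd_old_french = between_sd_old_french,
               sex_effect = sex_effect, age_slope = age_slope,
               site_offsets = site_offsets,
               education_slope = education_slope,
               race_offsets = race_offsets,
               maternal_slope = maternal_slope, iq_slope = iq_slope,
               site_probs = site_probs, iq_present = iq_present,
               clinical_rho = clinical_rho)
  class(spec) <- "generator_spec"
  spec
}

#' Default per-cohort parameter table
#'
#' Cohort sizes and lexical targets follow the analytic sample of the
#' emulated study (HC 164 / CHR 134 / ROP 86; Germanic 0.701/0.724/0.724,
#' Old French 0.190/0.172/0.173); demographics, antipsychotic rates,
#' functioning and symptom score distributions follow its demographic table.
#'
#' @return data.frame, one row per cohort.
#' @export
default_cohort_table <- function() {
  data.frame(
    cohort = c("HC", "CHR", "ROP"),
    n = c(164L, 134L, 86L),
    p_germanic = c(0.701, 0.724, 0.724),
    p_old_french = c(0.190, 0.172, 0.173),
    age_mean = c(23.4, 21.1, 22.4),
    age_sd = c(4.8, 4.6, 4.8),
    pct_female = c(0.624, 0.500, 0.522),
    education_mean = c(14.3, 12.2, 11.9),
    education_sd = c(2.7, 2.8, 2.7),
    maternal_mean = c(14.8, 14.0, 13.1),
    maternal_sd = c(2.7, 2.8, 3.2),
    iq_mean = c(112.3, 106.1, 101.5),
    iq_sd = c(11.6, 9.7, 11.4),
    antipsychotic_rate = c(0, 0.153, 0.761),
    gfr_mean = c(8.3, 6.5, 5.8), gfr_sd = c(0.9, 1.6, 1.9),
    gfs_mean = c(8.2, 6.4, 6.0), gfs_sd = c(0.7, 1.4, 1.4),
    pos_mean = c(0.7, 12.7, 15.1), pos_sd = c(1.2, 3.6, 3.1),
    neg_mean = c(0.6, 11.7, 12.7), neg_sd = c(1.3, 6.0, 4.3),
    race_asian = c(0.482, 0.224, 0.151),
    race_black = c(0.085, 0.082, 0.128),
    race_white = c(0.415, 0.567, 0.686),
    race_other = c(0.018, 0.127, 0.035),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic lexicon and frequency table
#'
#' Builds a vocabulary of `vocab_size` synthetic word forms, each with a POS
#' class, an origin class (content words follow the spec's type mixture;
#' function words are predominantly Germanic, as in English), and a Zipfian
#' corpus count (count of rank r proportional to r^-s). The etymology
#' lexicon and the frequency table are mutually consistent: words of class
#' UNKNOWN are present in the frequency table but absent from the lexicon.
#'
#' @param spec A `generator_spec`.
#' @param seed Integer seed; fixes the vocabulary byte-for-byte.
#' @return List with `lexicon` (an `etymology_lexicon`), `freq_table`
#'   (a `frequency_table`), `vocab` (data.frame word/pos/class/count) and
#'   `tagger` (a lookup tagger over the vocabulary).
#' @export
generate_lexicon <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  nw <- spec$vocab_size
  word <- sprintf("w%05d", seq_len(nw))
  pos <- sample(names(spec$pos_dist), nw, replace = TRUE,
                prob = spec$pos_dist)
  class_ <- character(nw)
  content <- pos != "OTHER"
  class_[content] <- sample(names(spec$type_mixture), sum(content),
                            replace = TRUE, prob = spec$type_mixture)
  # function words skew heavily Germanic in English
  class_[!content] <- sample(c("GERMANIC_ONLY", "NEITHER"), sum(!content),
                             replace = TRUE, prob = c(0.9, 0.1))
  # guarantee every content (class, pos) cell is populated
  for (cl in names(spec$type_mixture))
    for (p in setdiff(names(spec$pos_dist), "OTHER"))
      if (!any(class_ == cl & pos == p)) {
        idx <- sample(which(content), 1)
        class_[idx] <- cl
        pos[idx] <- p
      }
  rank <- sample(nw)  # ranks shuffled so rank is independent of class
  counts <- pmax(1, round(1e6 / rank^spec$zipf_exponent))
  vocab <- data.frame(word = word, pos = pos, class = class_,
                      rank = rank, count = counts, stringsAsFactors = FALSE)
  entries <- list()
  origin_for <- c(GERMANIC_ONLY = "Old English",
                  OLD_FRENCH_ONLY = "Old French",
                  NEITHER = "Japanese")
  in_lex <- class_ != "UNKNOWN"
  entries <- lapply(seq_len(nw)[in_lex], function(i) {
    if (class_[i] == "BOTH") c("Old English", "Old French")
    else origin_for[[class_[i]]]
  })
  names(entries) <- word[in_lex]
  lex <- etymology_lexicon(entries)
  ft <- frequency_table(stats::setNames(counts, word))
  tagger <- lookup_tagger(data.frame(surface = word, lemma = word,
                                     upos = pos, stringsAsFactors = FALSE))
  list(lexicon = lex, freq_table = ft, vocab = vocab, tagger = tagger)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic cohort of transcripts and participants
#'
#' For each participant: demographics are drawn from the cohort's
#' distributions; the participant's true Germanic and Old-French token
#' mixtures start from the cohort targets, receive an anti-correlated
#' between-participant deviation (one latent normal raises the Germanic
#' logit while lowering the Old-French logit, mirroring the strong negative
#' correlation of the two proportions in speech), and receive additive
#' covariate effects on the logit scale. Tokens are then drawn word by word:
#' POS class first, origin class for content tokens from the participant's
#' mixture, and the word within the (class, POS) cell with Zipfian weights.
#' Role functioning is coupled to the Old-French mixture in the clinical
#' cohorts through a Gaussian copula calibrated to the target Spearman rho.
#'
#' @param spec A `generator_spec`.
#' @param seed Integer seed; fixes everything end-to-end.
#' @param lexgen Output of [generate_lexicon()]; generated from `spec` and
#'   `seed` when not supplied.
#' @param emit_text Also render each transcript as speaker-labelled dialogue
#'   text with templated punctuation (exercises the preprocessing module).
#' @return A `cohort_simulation`: list with `participants` (metadata
#'   data.frame), `transcripts` (list of per-participant token streams and
#'   optional text), `ground_truth` (true per-participant mixtures),
#'   `lexicon`, `freq_table`, `tagger`, `spec`, `seed`.
#' @export
generate_cohort <- function(spec = generator_spec(), seed = 1L,
                            lexgen = generate_lexicon(spec, seed),
                            emit_text = TRUE) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$tokens_mean < 50 || spec$tokens_min < 50)
    stop("token budget below 50 per transcript: metrics unstable")
  if (any(spec$cohorts$n < 2)) stop("cohort sizes must be at least 2")
  set.seed(seed + 1L)
  co <- spec$cohorts
  n_total <- sum(co$n)
  cohort <- rep(co$cohort, co$n)
  row <- match(cohort, co$cohort)

  sex <- ifelse(stats::runif(n_total) < co$pct_female[row], "female", "male")
  age <- stats::rnorm(n_total, co$age_mean[row], co$age_sd[row])
  age <- pmax(15, age)
  site <- sample(names(spec$site_probs), n_total, replace = TRUE,
                 prob = spec$site_probs)
  education <- pmax(6, stats::rnorm(n_total, co$education_mean[row],
                                    co$education_sd[row]))
  race_p <- cbind(co$race_asian, co$race_black, co$race_white, co$race_other)
  race <- vapply(seq_len(n_total), function(i)
    sample(c("Asian", "Black", "White", "Other"), 1,
           prob = race_p[row[i], ]), character(1))
  maternal <- pmax(6, stats::rnorm(n_total, co$maternal_mean[row],
                                   co$maternal_sd[row]))
  antipsychotic <- ifelse(
    stats::runif(n_total) < co$antipsychotic_rate[row], "yes", "no")
  has_iq <- stats::runif(n_total) < spec$iq_present
  iq <- ifelse(has_iq, stats::rnorm(n_total, co$iq_mean[row], co$iq_sd[row]),
               NA_real_)

  # true mixtures: anti-correlated participant deviation + covariate shifts
  pg0 <- co$p_germanic[row]
  pof0 <- co$p_old_french[row]
  sd_lg <- spec$between_sd_germanic / (pg0 * (1 - pg0))
  sd_lof <- spec$between_sd_old_french / (pof0 * (1 - pof0))
  u <- stats::rnorm(n_total)
  delta <- spec$sex_effect * (sex == "female") +
    spec$age_slope * (age - mean(age)) +
    spec$site_offsets[site] +
    spec$education_slope * (education - mean(education)) +
    spec$race_offsets[race] +
    spec$maternal_slope * (maternal - mean(maternal)) +
    ifelse(has_iq, spec$iq_slope * (iq - mean(iq, na.rm = TRUE)), 0)
  # anchor covariate effects at the HC cohort: HC mixture means stay on
  # target, clinical cohorts carry covariate-mediated shifts that the
  # HC-anchored adjustment is designed to remove
  delta <- unname(delta)
  delta <- delta - mean(delta[cohort == "HC"])
  lg <- logit(pg0) + u * sd_lg + delta
  lof <- logit(pof0) - u * sd_lof - delta
  p_g <- inv_logit(lg)
  p_of <- inv_logit(lof)
  squeeze <- p_g + p_of > 0.98
  if (any(squeeze)) {
    sc <- 0.98 / (p_g[squeeze] + p_of[squeeze])
    p_g[squeeze] <- p_g[squeeze] * sc
    p_of[squeeze] <- p_of[squeeze] * sc
  }

  # clinical scores; role functioning coupled to the Old-French latent.
  # The target Spearman rho refers to the MEASURED Old-French proportion,
  # which carries binomial counting noise and covariate-shift variance the
  # shared latent does not; the copula strength is therefore deflated by the
  # predictable attenuation so the observed coupling lands on target.
  clin <- cohort %in% c("CHR", "ROP")
  n_content_exp <- spec$tokens_mean * (1 - spec$pos_dist[["OTHER"]])
  pof_c <- mean(pof0[clin])
  attn <- mean(sd_lof[clin]) /
    sqrt(mean(sd_lof[clin])^2 + stats::var(delta[clin]) +
           1 / (pof_c * (1 - pof_c) * n_content_exp))
  r_lat <- min(0.99, 2 * sin(pi * spec$clinical_rho / 6) / attn)
  z_of <- -u  # the latent that raises Old-French use
  eps <- stats::rnorm(n_total)
  gfr_lat <- ifelse(clin, r_lat * z_of + sqrt(1 - r_lat^2) * eps, eps)
  gf_role <- pmin(10, pmax(1, round(co$gfr_mean[row] +
                                      co$gfr_sd[row] * gfr_lat)))
  gf_social <- pmin(10, pmax(1, round(stats::rnorm(
    n_total, co$gfs_mean[row], co$gfs_sd[row]))))
  positive_sx <- pmax(0, stats::rnorm(n_total, co$pos_mean[row],
                                      co$pos_sd[row]))
  negative_sx <- pmax(0, stats::rnorm(n_total, co$neg_mean[row],
                                      co$neg_sd[row]))

  n_tokens <- pmax(spec$tokens_min,
                   round(stats::rnorm(n_total, spec$tokens_mean,
                                      spec$tokens_sd)))

  vocab <- lexgen$vocab
  content_pos <- setdiff(names(spec$pos_dist), "OTHER")
  cell <- split(seq_len(nrow(vocab)),
                list(class = vocab$class, pos = vocab$pos), drop = TRUE)
  cell_w <- lapply(cell, function(ix) vocab$count[ix])
  other_ix <- which(vocab$pos == "OTHER")
  other_w <- vocab$count[other_ix]

  pid <- sprintf("P%03d", seq_len(n_total))
  transcripts <- vector("list", n_total)
  rest <- spec$rest_split
  for (i in seq_len(n_total)) {
    nt <- n_tokens[i]
    pos_i <- sample(names(spec$pos_dist), nt, replace = TRUE,
                    prob = spec$pos_dist)
    words <- character(nt)
    is_content <- pos_i != "OTHER"
    nc <- sum(is_content)
    p_rest <- 1 - p_g[i] - p_of[i]
    cls <- sample(c("GERMANIC_ONLY", "OLD_FRENCH_ONLY", names(rest)),
                  nc, replace = TRUE,
                  prob = c(p_g[i], p_of[i], p_rest * rest))
    cidx <- which(is_content)
    for (cl in unique(cls)) {
      sel <- cidx[cls == cl]
      pos_sel <- pos_i[sel]
      for (p in unique(pos_sel)) {
        key <- paste(cl, p, sep = ".")
        ix <- cell[[key]]
        here <- sel[pos_sel == p]
        words[here] <- vocab$word[ix[sample.int(
          length(ix), length(here), replace = TRUE, prob = cell_w[[key]])]]
      }
    }
    n_other <- nt - nc
    if (n_other > 0)
      words[!is_content] <- vocab$word[other_ix[sample.int(
        length(other_ix), n_other, replace = TRUE, prob = other_w)]]
    transcripts[[i]] <- list(
      transcript_id = pid[i], words = words, pos = pos_i,
      text = if (emit_text) detokenize_dialogue(words) else NULL)
  }

  participants <- data.frame(
    participant_id = pid, transcript_id = pid, cohort = cohort,
    sex = sex, age = age, site = site, education = education, race = race,
    maternal_education = maternal, antipsychotic = antipsychotic, iq = iq,
    gf_role = gf_role, gf_social = gf_social,
    positive_sx = positive_sx, negative_sx = negative_sx,
    stringsAsFactors = FALSE)
  ground_truth <- data.frame(
    participant_id = pid, cohort = cohort,
    true_p_germanic = p_g, true_p_old_french = p_of,
    n_tokens = n_tokens, stringsAsFactors = FALSE)
  structure(list(participants = participants, transcripts = transcripts,
                 ground_truth = ground_truth,
                 lexicon = lexgen$lexicon, freq_table = lexgen$freq_table,
                 tagger = lexgen$tagger, vocab = lexgen$vocab,
                 spec = spec, seed = seed),
            class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat("<cohort_simulation> ", nrow(x$participants), " participants (",
      paste(sprintf("%s=%d", names(table(x$participants$cohort)),
                    table(x$participants$cohort)), collapse = ", "),
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# render a token stream as speaker-labelled dialogue with simple punctuation
detokenize_dialogue <- function(words) {
  n <- length(words)
  out <- character(0)
  lines <- c("Interviewer: How have things been going for you lately?")
  i <- 1L
  while (i <= n) {
    len <- min(sample(6:14, 1), n - i + 1L)
    sent <- words[i:(i + len - 1L)]
    sent[1] <- paste0(toupper(substr(sent[1], 1, 1)),
                      substr(sent[1], 2, nchar(sent[1])))
    out <- c(out, paste0(paste(sent, collapse = " "), "."))
    i <- i + len
    if (length(out) >= 8 || i > n) {
      lines <- c(lines, paste("Participant:", paste(out, collapse = " ")))
      out <- character(0)
      if (i <= n)
        lines <- c(lines, "Interviewer: Can you tell me more about that?")
    }
  }
  paste(lines, collapse = "\n")
}

#' Lexical profiles of a simulated cohort, from token streams
#'
#' Bypasses text rendering and preprocessing: builds token records directly
#' from each simulated token stream (the generator's words are their own
#' lemmas) and computes each participant's lexical profile.
#'
#' @param sim A `cohort_simulation`.
#' @return data.frame of one [lexical_profile()] row per participant.
#' @export
cohort_profiles <- function(sim) {
  stopifnot(inherits(sim, "cohort_simulation"))
  rows <- lapply(sim$transcripts, function(tr) {
    tokens <- data.frame(index = seq_along(tr$words) - 1L,
                         surface = tr$words, lemma = tr$words,
                         upos = tr$pos, stringsAsFactors = FALSE)
    class(tokens) <- c("token_records", "data.frame")
    lexical_profile(tokens, sim$lexicon, sim$freq_table,
                    transcript_id = tr$transcript_id)
  })
  do.call(rbind, rows)
}

#' Write a simulated dataset to a directory
#'
#' Produces a self-contained dataset: `transcripts/` (speaker-labelled
#' dialogue text, one file per participant), `lexicon.tsv`, `freqs.tsv`,
#' `participants.csv`, `ground_truth.json` and `spec.yaml`.
#'
#' @param sim A `cohort_simulation` generated with `emit_text = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_simulation"))
  if (is.null(sim$transcripts[[1]]$text))
    stop("simulation was generated with emit_text = FALSE")
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  for (tr in sim$transcripts)
    writeLines(tr$text, file.path(dir, "transcripts",
                                  paste0(tr$transcript_id, ".txt")))
  write_lexicon(sim$lexicon, file.path(dir, "lexicon.tsv"))
  write_frequency_table(sim$freq_table, file.path(dir, "freqs.tsv"))
  # the vocabulary doubles as the lookup-tagger table for this dataset
  utils::write.table(
    data.frame(surface = sim$vocab$word, lemma = sim$vocab$word,
               upos = sim$vocab$pos, stringsAsFactors = FALSE),
    file.path(dir, "tagger.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.csv(sim$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  spec_plain <- sim$spec
  class(spec_plain) <- NULL
  spec_plain$cohorts <- as.list(spec_plain$cohorts)
  yaml::write_yaml(c(spec_plain, seed = sim$seed),
                   file.path(dir, "spec.yaml"))
  invisible(dir)
}
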