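# shared fixtures, built in code

# toy lexicon encoding the printed etymologies of the four example words,
# plus entries for the bundled tagger's content vocabulary
toy_lexicon <- function() {
  etymology_lexicon(list(
    ask = "Old English",
    inquire = "Old French",
    talkative = c("Old English", "Old French"),
    karaoke = "Japanese",
    dog = "Old English",
    cat = "Old English",
    run = "Old English",
    be = "Old English",
    week = "Old English",
    day = "Old English",
    think = "Old English",
    big = "Old Norse",
    good = "Old English",
    fine = "Old French",
    busy = "Old English",
    formal = "Old French",
    quickly = "Old English",
    really = "Old French",
    school = "Old English",
    friend = "Old English",
    person = "Old French",
    time = "Old English"))
}

toy_freq_table <- function() {
  frequency_table(c(ask = 5000, inquire = 50, talkative = 20, karaoke = 10,
                    dog = 2000, run = 3000, be = 50000, week = 1500,
                    quickly = 400, fine = 800, busy = 300, school = 1200,
                    good = 4000, think = 2500, friend = 900, time = 6000),
                  total = 1e6)
}

# token records built directly (bypassing the tagger) for counting tests
make_tokens <- function(lemmas, upos = rep("NOUN", length(lemmas))) {
  out <- data.frame(index = seq_along(lemmas) - 1L, surface = lemmas,
                    lemma = lemmas, upos = upos, stringsAsFactors = FALSE)
  class(out) <- c("token_records", "data.frame")
  out
}

# small, fast generator conditions for unit tests (cohort targets and
# mixture structure kept; sizes and transcript lengths scaled down)
small_spec <- function(n = c(30L, 30L, 30L), tokens_mean = 400, ...) {
  co <- default_cohort_table()
  co$n <- n
  generator_spec(vocab_size = 500, cohorts = co,
                 tokens_mean = tokens_mean, tokens_sd = 40,
                 tokens_min = 200, ...)
}

# brute-force oracles, independent of the implementation paths they check
oracle_honore <- function(lemmas, base = exp(1)) {
  n <- length(lemmas)
  uniq <- unique(lemmas)
  v <- length(uniq)
  v1 <- sum(vapply(uniq, function(u) sum(lemmas == u) == 1L, logical(1)))
  100 * log(n, base) / (1 - v1 / v)
}

oracle_perplexity <- function(probs) {
  # product form: Pi = (prod w_i)^(-1/n)
  prod(probs)^(-1 / length(probs))
}
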