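# build a participant table directly; lexical columns are plain numerics here
make_records <- function(n_hc = 30, n_chr = 20, n_rop = 15, seed = 1) {
  set.seed(seed)
  n <- n_hc + n_chr + n_rop
  data.frame(
    participant_id = sprintf("P%03d", 1:n),
    cohort = rep(c("HC", "CHR", "ROP"), c(n_hc, n_chr, n_rop)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = runif(n, 16, 35),
    site = sample(c("NewYork", "Melbourne", "Toronto"), n, replace = TRUE),
    education = runif(n, 10, 18),
    race = sample(c("Asian", "Black", "White", "Other"), n, replace = TRUE,
                  prob = c(.4, .1, .45, .05)),
    maternal_education = runif(n, 10, 18),
    antipsychotic = ifelse(rep(c(FALSE, TRUE, TRUE), c(n_hc, n_chr, n_rop)) &
                             runif(n) < 0.4, "yes", "no"),
    iq = ifelse(runif(n) < 0.7, rnorm(n, 105, 10), NA),
    p_germanic = rnorm(n, 0.70, 0.03),
    p_old_french = rnorm(n, 0.19, 0.025),
    honore_R = rnorm(n, 680, 50),
    perplexity = rnorm(n, 110, 15),
    stringsAsFactors = FALSE)
}

test_that("association tests give the expected statistics on fixtures", {
  # feature identical across categories: t statistic 0
  res <- test_association(rep(5, 10), rep(c("a", "b"), each = 5),
                          "categorical")
  expect_equal(res$statistic, 0)

  # perfectly rank-correlated pairs: rho = 1
  res <- test_association(c(1, 4, 9, 16, 25), 1:5, "continuous")
  expect_equal(res$statistic, 1)

  # hand ANOVA on {1,2,3},{2,3,4},{3,4,5}: between-MS 3, within-MS 1
  res <- test_association(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                          rep(c("a", "b", "c"), each = 3), "categorical")
  expect_equal(res$statistic, 3.0, tolerance = 1e-12)
  expect_identical(res$method, "anova")

  expect_error(test_association(1:6, rep("a", 6), "categorical"),
               "constant covariate")
  expect_error(test_association(1:6, rep(2, 6), "continuous"),
               "constant covariate")
})

test_that("categorical adjustment shifts by HC median differences", {
  rec <- data.frame(
    cohort = c(rep("HC", 8), rep("ROP", 2)),
    sex = c(rep("female", 5), rep("male", 3), "male", "female"),
    feat = c(0.70, 0.72, 0.74, 0.71, 0.73,  # HC female, median 0.72
             0.69, 0.70, 0.71,              # HC male, median 0.70
             0.80, 0.80),
    stringsAsFactors = FALSE)
  m <- fit_categorical_adjustment(rec, "feat", "sex")
  expect_identical(m$reference, "female")  # largest HC category
  expect_equal(unname(m$offsets["male"]), -0.02)
  adj <- apply_adjustment(m, rec)
  # male values are shifted +0.02, female untouched
  expect_equal(adj$feat[9], 0.82)
  expect_equal(adj$feat[10], 0.80)
  # post-adjustment HC per-category medians coincide
  hc <- adj[adj$cohort == "HC", ]
  expect_equal(diff(range(tapply(hc$feat, hc$sex, median))), 0)

  # equal HC medians: identity transform
  rec2 <- rec
  rec2$feat[6:8] <- c(0.70, 0.72, 0.74)
  m2 <- fit_categorical_adjustment(rec2, "feat", "sex")
  expect_equal(apply_adjustment(m2, rec2)$feat, rec2$feat)

  # category unseen in HC is an error naming it
  rec3 <- rbind(rec, data.frame(cohort = "ROP", sex = "nonbinary",
                                feat = 0.7))
  expect_error(fit_categorical_adjustment(rec3, "feat", "sex"), "nonbinary")
})

test_that("HC per-category medians equalize on random fixtures", {
  set.seed(53)
  for (i in 1:10) {
    rec <- make_records(seed = 100 + i)
    m <- fit_categorical_adjustment(rec, "p_germanic", "site")
    adj <- apply_adjustment(m, rec)
    hc <- adj[adj$cohort == "HC", ]
    med <- tapply(hc$p_germanic, hc$site, median)
    expect_lt(diff(range(med)), 1e-12)
  }
})

test_that("continuous adjustment residualizes against the HC line", {
  rec <- make_records(seed = 5)
  # noiseless HC feature: all adjusted HC values collapse to the HC mean
  rec$feat <- ifelse(rec$cohort == "HC", 0.5 + 0.01 * rec$age,
                     0.6 + 0.01 * rec$age)
  m <- fit_continuous_adjustment(rec, "feat", "age")
  adj <- apply_adjustment(m, rec)
  hc_mean <- mean(rec$feat[rec$cohort == "HC"])
  expect_equal(adj$feat[adj$cohort == "HC"],
               rep(hc_mean, sum(rec$cohort == "HC")), tolerance = 1e-10)
  # non-HC rows are adjusted with the HC-fitted line, not refit:
  # their 0.1 offset from the HC line survives adjustment
  expect_equal(adj$feat[adj$cohort != "HC"],
               rep(hc_mean + 0.1, sum(rec$cohort != "HC")),
               tolerance = 1e-10)

  # zero-slope fit is the identity
  rec$flat <- ave(rec$feat, rec$cohort)  # constant within cohort
  m0 <- fit_continuous_adjustment(rec, "flat", "age")
  expect_equal(m0$slope, 0, tolerance = 1e-12)
  expect_equal(apply_adjustment(m0, rec)$flat, rec$flat, tolerance = 1e-12)

  expect_error(fit_continuous_adjustment(rec[rec$cohort == "ROP", ],
                                         "feat", "age"), "at least 3 HC")
})

test_that("adjustment preserves the HC anchor", {
  rec <- make_records(seed = 9)
  m <- fit_continuous_adjustment(rec, "p_germanic", "age")
  adj <- apply_adjustment(m, rec)
  expect_equal(mean(adj$p_germanic[adj$cohort == "HC"]),
               mean(rec$p_germanic[rec$cohort == "HC"]), tolerance = 1e-10)
})

test_that("sequential adjustment gates on etymology associations", {
  # no associations: output equals input
  rec <- make_records(seed = 42)
  res <- sequential_adjust(rec)
  if (all(res$audit$decision[res$audit$scope == "whole_dataset"] ==
            "no_adjust"))
    expect_equal(res$records$p_germanic, rec$p_germanic)

  # inject an age slope everywhere: adjustment drives HC rho to ~0
  set.seed(77)
  n <- 200
  rec2 <- data.frame(
    cohort = rep(c("HC", "CHR"), each = n / 2),
    age = runif(n, 16, 35),
    p_germanic = NA, p_old_french = NA,
    stringsAsFactors = FALSE)
  rec2$p_germanic <- 0.7 + 0.004 * (rec2$age - 25) + rnorm(n, 0, 0.01)
  rec2$p_old_french <- 0.19 - 0.003 * (rec2$age - 25) + rnorm(n, 0, 0.01)
  ord <- default_covariate_order()
  res2 <- sequential_adjust(rec2,
                            lexical_features = c("p_germanic",
                                                 "p_old_french"),
                            covariate_order = ord[ord$covariate == "age", ])
  expect_identical(unique(res2$audit$decision), "adjust")
  hc <- res2$records[res2$records$cohort == "HC", ]
  expect_lt(abs(cor(hc$p_germanic, hc$age, method = "spearman")), 0.05)
  expect_lt(abs(cor(hc$p_old_french, hc$age, method = "spearman")), 0.05)

  # a covariate constructed with no effect is tested but never adjusted
  rec2$maternal_education <- runif(n, 10, 18)
  res3 <- sequential_adjust(rec2,
                            lexical_features = c("p_germanic",
                                                 "p_old_french"),
                            covariate_order = ord[ord$covariate ==
                                                    "maternal_education", ])
  mat <- res3$audit[res3$audit$covariate == "maternal_education", ]
  expect_true(nrow(mat) > 0)
  if (all(mat$p >= 0.05)) {
    expect_identical(unique(mat$decision), "no_adjust")
    expect_equal(res3$records$p_germanic, rec2$p_germanic)
  }
})

test_that("race categories merge and antipsychotic is audited, not adjusted", {
  rec <- make_records(seed = 13)
  res <- sequential_adjust(rec)
  expect_true(all(res$records$race != "Black") &&
                all(res$records$race != "Other"))
  expect_true("Black/Other" %in% res$records$race)
  anti <- res$audit[res$audit$covariate == "antipsychotic", ]
  expect_true(all(anti$scope %in% c("within_CHR", "within_ROP")))
  expect_true(all(anti$decision == "never_adjusted"))
  expect_false(any(grepl("antipsychotic", names(res$models))))
})
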