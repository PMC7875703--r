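test_that("cleansing rejects unreasonable vitals with the right reason codes", {
  v <- mk_visits(8L,
                 cc = c("chest pain", "", "fever", "fall", "dyspnea", "cough",
                        "weakness", "rash"),
                 sbp = c(120, 120, 310, 80, NA, 120, 120, 120),
                 dbp = c(80, 80, 80, 90, NA, 70, 70, 70),
                 hr = c(80, 80, 80, 80, 260, NA, 80, 80),
                 rr = c(18, 18, 18, 18, 18, 120, 18, 18),
                 bt = c(37, 37, 37, 37, 37, 37, 19.5, 49))
  cl <- cleanse_visits(v)
  expect_equal(nrow(cl$kept) + nrow(cl$rejected), nrow(v))
  expect_equal(cl$rejected$visit_id, sprintf("t%03d", c(2, 3, 4, 5, 6, 7, 8)))
  expect_equal(cl$rejected$reason,
               c("MISSING_CC", "SBP_GT_300", "DBP_GT_SBP", "HR_GT_250",
                 "RR_GT_100", "BT_OUT_OF_RANGE", "BT_OUT_OF_RANGE"))
  # weight/height thresholds
  v2 <- mk_visits(2L, weight = c(410, 100), height = c(170, 260))
  expect_equal(cleanse_visits(v2)$rejected$reason, c("WT_GT_400", "HT_GT_250"))
})

test_that("visits with missing vitals but a chief complaint are kept", {
  v <- mk_visits(2L, cc = c("abdominal pain", "syncope"),
                 bt = c(NA, 37), hr = c(NA, 80))
  cl <- cleanse_visits(v)
  expect_equal(nrow(cl$kept), 2L)
  expect_equal(nrow(cl$rejected), 0L)
})

test_that("cleansing is idempotent and preserves order", {
  co <- generate_cohort(cohort_config(n_visits = 200, invalid_rate = 0.2, seed = 5))
  cl <- cleanse_visits(co$visits)
  expect_equal(nrow(cleanse_visits(cl$kept)$rejected), 0L)
  expect_equal(cl$kept$visit_id,
               co$visits$visit_id[co$visits$visit_id %in% cl$kept$visit_id])
})

test_that("revisit deduplication keeps the last flag per account", {
  v <- mk_visits(3L, account_id = c("A", "A", "B"), revisit_flag = c(0L, 1L, 0L))
  out <- deduplicate_revisits(v)
  expect_equal(out$visit_id, c("t002", "t003"))

  # enumerate: 5 accounts x 3 flags, expected flag always the max
  v2 <- mk_visits(15L, account_id = rep(LETTERS[1:5], each = 3L),
                  revisit_flag = rep(0:2, 5L))
  out2 <- deduplicate_revisits(v2)
  expect_equal(nrow(out2), 5L)
  expect_true(all(out2$revisit_flag == 2L))
  expect_false(anyDuplicated(out2$account_id) > 0)

  expect_equal(deduplicate_revisits(v[3, ])$visit_id, "t003")
  vdup <- mk_visits(2L, account_id = c("A", "A"), revisit_flag = c(1L, 1L))
  expect_error(deduplicate_revisits(vdup), "DUPLICATE_KEY")
})

test_that("history selection keeps strictly pre-triage records in order", {
  rec <- data.frame(time = sprintf("2016-01-0%dT00:00:00", c(1, 2, 5)),
                    text = c("a", "b", "c"))
  expect_equal(select_history(rec, "2016-01-03T00:00:00"), c("a", "b"))
  expect_equal(select_history(rec, "2015-12-01T00:00:00"), character(0))
  expect_equal(select_history(NULL, "2016-01-03T00:00:00"), character(0))

  # brute-force comparison on shuffled random timestamps
  set.seed(4)
  tt <- as.POSIXct("2016-01-01", tz = "UTC") + sample(stats::runif(10, 0, 1e6))
  rec2 <- data.frame(time = format(tt, "%Y-%m-%dT%H:%M:%S"),
                     text = sprintf("h%02d", seq_len(10)))
  triage <- sort(tt)[6] # strictly above 5, below the rest
  got <- select_history(rec2, format(triage, "%Y-%m-%dT%H:%M:%S"))
  want <- rec2$text[order(tt)][1:5]
  expect_equal(got, want)
})

test_that("critical-care labels honour the window, union, and nhamcs mode", {
  tt <- "2016-01-10T08:00:00"
  day <- 86400
  v <- mk_visits(5L, triage_time = rep(tt, 5),
                 icu_time = c("2016-01-12T08:00:00", NA, NA, NA, NA),
                 death_time = c(NA, "2016-01-20T08:00:00", NA,
                                "2016-01-13T08:00:00", "2016-01-13T08:00:01"))
  expect_equal(label_critical_outcome(v), c(1L, 0L, 0L, 1L, 0L))
  # boundary inclusive at exactly 3.0 days; monotone in window_days
  for (w in c(3, 5, 10, 30))
    expect_true(all(label_critical_outcome(v, w) >=
                    label_critical_outcome(v, 3)))
  vn <- mk_visits(3L, icu_direct = c(TRUE, FALSE, FALSE),
                  hosp_death = c(FALSE, TRUE, FALSE))
  expect_equal(label_critical_outcome(vn, mode = "nhamcs"), c(1L, 1L, 0L))
})

test_that("cohort stats discard missing values and imputation fills means", {
  v <- mk_visits(4L, hr = c(90, 100, NA, NA), sbp = c(NA, 120, 130, 140))
  st <- cohort_stats(v)
  expect_equal(st$mean[st$field == "hr"], 95)
  expect_equal(st$mean[st$field == "sbp"], 130)
  expect_true(all(st$sd >= 0, na.rm = TRUE))

  m <- impute_and_perturb(mk_visits(1L, sbp = 120), mk_stats(), 0)
  expect_equal(unname(m[1, "hr"]), 95.8)   # training mean fills the gap
  expect_equal(unname(m[1, "sbp"]), 120)   # present fields untouched
  expect_false(anyNA(m))
  st_bad <- mk_stats()[-3, ]
  expect_error(impute_and_perturb(mk_visits(1L), st_bad, 0), "INCOMPLETE_STATS")
})

test_that("perturbation noise matches the contracted scale", {
  st <- mk_stats()
  v <- mk_visits(1L, sbp = 135.4)
  draws <- vapply(seq_len(10000L), function(i) {
    impute_and_perturb(vitals_matrix(v), st, 0.1, seed = i)[1, "sbp"]
  }, numeric(1))
  expect_lt(abs(stats::sd(draws) / (0.1 * 27.3) - 1), 0.05)
  # gender code is never perturbed
  g <- vapply(seq_len(200L), function(i)
    impute_and_perturb(mk_visits(1L, gender = "male"), st, 0.5, seed = i)[1, "gender"],
    numeric(1))
  expect_true(all(g == 1))
  # zero noise is the identity on present fields and deterministic
  m1 <- impute_and_perturb(mk_visits(2L, sbp = c(100, 110)), st, 0)
  m2 <- impute_and_perturb(mk_visits(2L, sbp = c(100, 110)), st, 0)
  expect_identical(m1, m2)
})

test_that("split sizes reproduce the published tables and always sum", {
  expect_equal(split_sizes(1019437), list(n_train = 815550, n_val = 101943, n_test = 101944))
  expect_equal(split_sizes(297508), list(n_train = 238006, n_val = 29751, n_test = 29751))
  expect_equal(split_sizes(10), list(n_train = 8, n_val = 1, n_test = 1))
  expect_equal(split_sizes(0), list(n_train = 0, n_val = 0, n_test = 0))
  for (n in c(1, 7, 99, 1234, 999983)) {
    s <- split_sizes(n)
    expect_equal(s$n_train + s$n_val + s$n_test, n)
  }
  man <- assign_splits(sprintf("v%03d", 1:100), seed = 3)
  expect_equal(sort(table(man$split), decreasing = TRUE)[[1]], 80)
  expect_identical(man, assign_splits(sprintf("v%03d", 1:100), seed = 3))
})

test_that("JSONL round-trip preserves the visit table", {
  co <- generate_cohort(cohort_config(n_visits = 30, invalid_rate = 0.1, seed = 8))
  path <- tempfile(fileext = ".jsonl")
  write_visits_jsonl(co$visits, path)
  back <- read_visits_jsonl(path)
  expect_equal(back$visit_id, co$visits$visit_id)
  expect_equal(back$chief_complaint, co$visits$chief_complaint)
  expect_equal(vitals_matrix(back), vitals_matrix(co$visits))
  expect_equal(as.numeric(back$triage_time), as.numeric(co$visits$triage_time),
               tolerance = 1)
  h0 <- co$visits$history[[1]]; h1 <- back$history[[1]]
  if (!is.null(h0)) expect_equal(h1$text, h0$text)
})
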