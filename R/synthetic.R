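# Seeded generator of EHR-like cohorts with known latent cluster structure.
#
# Emulates the statistical shape of an emergency-department triage table:
# vitals drawn from cluster-shifted truncated Gaussians anchored at
# published cohort means/SDs, cluster-specific symptom vocabulary for the
# chief complaint and past histories, field-level missingness, a rare
# critical-care outcome whose log-odds depend on the latent cluster, and an
# optional fraction of deliberately invalid records to exercise cleansing.

.vital_anchor <- function() {
  data.frame(
    field = vital_fields(),
    mean = c(43.7, 0.505, 135.4, 78.3, 95.8, 97.2, 19.5, 37.1,
             152.8, 52.5, 2.7, 14.7, 4.0, 4.9, 5.9),
    sd   = c(26.9, 0.5, 27.3, 15.8, 25.6, 3.64, 3.4, 1.0,
             26.6, 22.8, 3.2, 1.4, 0.3, 0.6, 0.5),
    lo   = c(0, 0, 60, 30, 30, 50, 5, 34, 40, 2, 0, 3, 1, 1, 1),
    hi   = c(110, 1, 300, 250, 250, 100, 60, 42, 250, 400, 10, 15, 4, 5, 6))
}

.default_vocab <- function(n_clusters) {
  sets <- list(
    c("chest", "pain", "dyspnea", "cough", "palpitations", "syncope", "orthopnea", "wheezing"),
    c("abdominal", "cramping", "nausea", "vomiting", "diarrhea", "melena", "distention", "anorexia"),
    c("headache", "dizziness", "weakness", "numbness", "seizure", "confusion", "aphasia", "ataxia"),
    c("fever", "chills", "rash", "myalgia", "pharyngitis", "rhinorrhea", "malaise", "sweats"))
  if (n_clusters > length(sets))
    for (k in (length(sets) + 1L):n_clusters)
      sets[[k]] <- sprintf("sym%02d%s", k, letters[1:8])
  sets[seq_len(n_clusters)]
}

#' Synthetic cohort configuration
#'
#' @param n_visits cohort size.
#' @param n_clusters number of latent disease clusters (>= 2).
#' @param cluster_separation effect size of the cluster shifts on the
#'   vitals, in per-field SD units (RMS over fields).
#' @param missing_rate per-field probability of a missing vital.
#' @param invalid_rate fraction of records given one deliberate
#'   threshold violation (or a blanked chief complaint).
#' @param history_rate Poisson mean of the per-visit past-history count.
#' @param outcome_base_rate target overall critical-care-outcome
#'   prevalence (the intercept is solved so the cluster-mixture prevalence
#'   equals this; default 1.6%).
#' @param outcome_cluster_shift per-cluster log-odds shifts (recycled).
#' @param vocab list of per-cluster token vectors; default built-in
#'   disjoint symptom vocabularies.
#' @param vocab_overlap fraction of each cluster's tokens drawn from a
#'   shared pool (0 = fully disjoint; degrades the text signal).
#' @param seed RNG seed; the cohort is a deterministic function of the
#'   configuration.
#' @return An object of class `ed_cohort_config`.
#' @export
cohort_config <- function(n_visits = 2000L, n_clusters = 4L,
                          cluster_separation = 2, missing_rate = 0.1,
                          invalid_rate = 0, history_rate = 1.2,
                          outcome_base_rate = 0.016,
                          outcome_cluster_shift = c(-2, -1, 1, 2),
                          vocab = NULL, vocab_overlap = 0, seed = 1L) {
  stopifnot(n_clusters >= 2L, missing_rate >= 0, missing_rate <= 1,
            invalid_rate >= 0, invalid_rate <= 1,
            vocab_overlap >= 0, vocab_overlap <= 1)
  if (is.null(vocab)) vocab <- .default_vocab(n_clusters)
  if (any(!vapply(vocab, length, 1L))) stop("empty cluster vocabulary")
  if (vocab_overlap > 0) {
    # share a fraction of every cluster's tokens from a common pool
    shared <- unlist(vocab)[seq_len(max(1L, round(vocab_overlap * 8)))]
    vocab <- lapply(vocab, function(v) {
      ns <- round(vocab_overlap * length(v))
      if (ns > 0L) v[seq_len(ns)] <- shared[seq_len(min(ns, length(shared)))]
      unique(v)
    })
  }
  structure(list(n_visits = as.integer(n_visits), n_clusters = as.integer(n_clusters),
                 cluster_separation = cluster_separation, missing_rate = missing_rate,
                 invalid_rate = invalid_rate, history_rate = history_rate,
                 outcome_base_rate = outcome_base_rate,
                 outcome_cluster_shift = rep_len(outcome_cluster_shift, n_clusters),
                 vocab = vocab, vocab_overlap = vocab_overlap,
                 seed = as.integer(seed)),
            class = "ed_cohort_config")
}

#' Generate a synthetic cohort
#'
#' @param config an [cohort_config()].
#' @return An object of class `ed_cohort`: list with `visits` (a visit
#'   table; the latent labels never appear in it), `latent_cluster`,
#'   `injected_reason` (the violation injected per visit, NA for clean
#'   records), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_visits
  K <- config$n_clusters
  anchor <- .vital_anchor()
  nf <- nrow(anchor)

  # per-cluster shift directions with unit RMS, scaled by the separation
  delta <- matrix(stats::rnorm(K * nf), K, nf)
  delta <- delta / sqrt(rowMeans(delta^2))
  delta[, anchor$field == "gender"] <- 0

  vocab <- config$vocab

  # intercept such that the cluster-mixture prevalence hits the target
  shift <- config$outcome_cluster_shift
  f <- function(b) mean(stats::plogis(b + shift)) - config$outcome_base_rate
  b0 <- stats::uniroot(f, c(-30, 30))$root

  cl <- sample.int(K, n, replace = TRUE)
  vit <- matrix(NA_real_, n, nf, dimnames = list(NULL, anchor$field))
  for (j in seq_len(nf)) {
    m <- anchor$mean[j] + config$cluster_separation * anchor$sd[j] * delta[cl, j]
    x <- stats::rnorm(n, m, anchor$sd[j])
    vit[, j] <- pmin(pmax(x, anchor$lo[j]), anchor$hi[j])
  }
  vit[, "dbp"] <- pmin(vit[, "dbp"], vit[, "sbp"] - 5)
  for (j in c("pain", "gcs", "eye", "verbal", "motor")) vit[, j] <- round(vit[, j])
  gender <- ifelse(stats::runif(n) < anchor$mean[anchor$field == "gender"],
                   "male", "female")

  # field-level missingness (gender included; chief complaint handled below)
  for (j in seq_len(nf)) {
    miss <- stats::runif(n) < config$missing_rate
    if (anchor$field[j] == "gender") gender[miss] <- NA else vit[miss, j] <- NA
  }

  cc <- vapply(seq_len(n), function(i) {
    nw <- sample(2:5, 1L)
    paste(sample(vocab[[cl[i]]], nw, replace = nw > length(vocab[[cl[i]]])),
          collapse = " ")
  }, character(1))

  t0 <- as.POSIXct("2016-06-01 00:00:00", tz = "UTC")
  triage <- t0 + stats::runif(n, 0, 365) * 86400
  hist <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1L, config$history_rate)
    if (k == 0L) return(NULL)
    data.frame(
      time = format(triage[i] - stats::runif(k, 30, 1000) * 86400,
                    "%Y-%m-%dT%H:%M:%S"),
      text = vapply(seq_len(k), function(z)
        paste("history of", paste(sample(vocab[[cl[i]]], sample(1:2, 1L)),
                                  collapse = " ")), character(1)),
      stringsAsFactors = FALSE)
  })

  outcome <- stats::rbinom(n, 1L, stats::plogis(b0 + shift[cl]))
  icu_time <- death_time <- rep(as.POSIXct(NA, tz = "UTC"), n)
  ev <- stats::runif(n)
  inwin <- which(outcome == 1L)
  icu_pick <- inwin[ev[inwin] < 0.5]
  dth_pick <- setdiff(inwin, icu_pick)
  icu_time[icu_pick] <- triage[icu_pick] + stats::runif(length(icu_pick), 0, 3) * 86400
  death_time[dth_pick] <- triage[dth_pick] + stats::runif(length(dth_pick), 0, 3) * 86400
  # a few late (out-of-window) events among the negatives
  late <- which(outcome == 0L & stats::runif(n) < 0.02)
  death_time[late] <- triage[late] + stats::runif(length(late), 4, 30) * 86400

  # deliberate violations to exercise cleansing
  reasons <- c("MISSING_CC", "SBP_GT_300", "DBP_GT_SBP", "HR_GT_250",
               "RR_GT_100", "BT_OUT_OF_RANGE", "WT_GT_400", "HT_GT_250")
  injected <- rep(NA_character_, n)
  bad <- which(stats::runif(n) < config$invalid_rate)
  for (i in bad) {
    r <- sample(reasons, 1L)
    injected[i] <- r
    switch(r,
      MISSING_CC = { cc[i] <- "" },
      SBP_GT_300 = { vit[i, "sbp"] <- stats::runif(1, 301, 400) },
      DBP_GT_SBP = { if (is.na(vit[i, "sbp"])) vit[i, "sbp"] <- 120
                     vit[i, "dbp"] <- vit[i, "sbp"] + stats::runif(1, 5, 30) },
      HR_GT_250 = { vit[i, "hr"] <- stats::runif(1, 251, 300) },
      RR_GT_100 = { vit[i, "rr"] <- stats::runif(1, 101, 150) },
      BT_OUT_OF_RANGE = { vit[i, "bt"] <- if (stats::runif(1) < 0.5)
        stats::runif(1, 10, 19.5) else stats::runif(1, 48.5, 55) },
      WT_GT_400 = { vit[i, "weight"] <- stats::runif(1, 401, 500) },
      HT_GT_250 = { vit[i, "height"] <- stats::runif(1, 251, 290) })
  }

  args <- list(visit_id = sprintf("v%06d", seq_len(n)),
               chief_complaint = cc,
               triage_time = triage, icu_time = icu_time, death_time = death_time,
               icu_direct = outcome == 1L & seq_len(n) %in% icu_pick,
               hosp_death = outcome == 1L & seq_len(n) %in% dth_pick,
               history = hist, gender = gender)
  for (f2 in setdiff(vital_fields(), "gender")) args[[f2]] <- vit[, f2]
  visits <- do.call(visit_table, args)
  structure(list(visits = visits, latent_cluster = cl,
                 injected_reason = injected, config = config),
            class = "ed_cohort")
}

#' Write a cohort to files
#'
#' Writes the visit JSONL consumed by the preprocessing functions plus a
#' separate latent-truth CSV (`visit_id`, `latent_cluster`,
#' `injected_reason`); the truth never enters the visit file.
#'
#' @param cohort an `ed_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
cohort_to_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vpath <- file.path(dir, "visits.jsonl")
  tpath <- file.path(dir, "truth.csv")
  write_visits_jsonl(cohort$visits, vpath)
  utils::write.csv(data.frame(visit_id = cohort$visits$visit_id,
                              latent_cluster = cohort$latent_cluster,
                              injected_reason = cohort$injected_reason,
                              stringsAsFactors = FALSE),
                   tpath, row.names = FALSE)
  invisible(c(visits = vpath, truth = tpath))
}
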