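# Conversion of NHAMCS-style survey rows into the package's visit table.

#' Default comorbidity phrase table
#'
#' Maps NHAMCS-style comorbidity flag names to the free-text past-history
#' phrase generated for a positive flag. Shipped as an editable CSV resource
#' (`extdata/nhamcs_phrases.csv`); users may pass their own table.
#'
#' @return data.frame with columns `flag`, `phrase`.
#' @export
nhamcs_phrase_table <- function() {
  utils::read.csv(system.file("extdata", "nhamcs_phrases.csv", package = "edembed"),
                  stringsAsFactors = FALSE)
}

.nhamcs_excluded <- c("dead_on_arrival", "left_before_seen", "against_medical_advice")
.nhamcs_known <- c(.nhamcs_excluded, "admit", "admit_icu", "discharge",
                   "transfer", "observation", "died_in_hospital")

#' Convert NHAMCS-style survey rows to a visit table
#'
#' Emulates the survey preprocessing: records disposed as dead on arrival,
#' left before being seen, or left against medical advice are excluded; the
#' coded reason-for-visit descriptions (`reason1`..`reason3`) are joined
#' into one free-text chief complaint; each positive comorbidity flag
#' becomes one past-history text via the phrase table; the standard
#' cleansing thresholds are then applied. Height, weight and the GCS
#' components are absent from the survey and stay missing (they are
#' mean-imputed downstream; the 15-slot structural layout is fixed).
#'
#' Survey rows carry no event timestamps, so the outcome is labeled in
#' "nhamcs" mode from the `icu_direct` (direct ICU admission) and
#' `hosp_death` (died in hospital) flags.
#'
#' @param records data.frame with columns `reason1`..`reason3`, `dispo`,
#'   the available vitals (`age`, `gender`, `sbp`, `dbp`, `hr`, `spo2`,
#'   `rr`, `bt`, `pain`, `gcs`), logical comorbidity columns named as in the
#'   phrase table, and logical `icu_direct`, `hosp_death`.
#' @param phrases phrase table (defaults to [nhamcs_phrase_table()]).
#' @return list with `visits` (cleansed visit table), `rejected` (failed the
#'   vitals/chief-complaint rules, with reason codes), and `excluded`
#'   (dropped by disposition).
#' @export
nhamcs_preprocess <- function(records, phrases = nhamcs_phrase_table()) {
  dispo <- as.character(records$dispo)
  unknown <- !is.na(dispo) & !(dispo %in% .nhamcs_known)
  if (any(unknown))
    warning(sprintf("unknown disposition code(s) kept: %s",
                    paste(unique(dispo[unknown]), collapse = ", ")))
  drop <- !is.na(dispo) & dispo %in% .nhamcs_excluded
  excluded <- records[drop, , drop = FALSE]
  rec <- records[!drop, , drop = FALSE]
  n <- nrow(rec)

  rcols <- intersect(c("reason1", "reason2", "reason3"), names(rec))
  cc <- vapply(seq_len(n), function(i) {
    parts <- unlist(rec[i, rcols], use.names = FALSE)
    parts <- parts[!is.na(parts) & nzchar(trimws(parts))]
    paste(parts, collapse = "; ")
  }, character(1))

  t0 <- as.POSIXct("2015-01-01 12:00:00", tz = "UTC")
  triage <- t0 + seq_len(n) * 3600
  hist <- lapply(seq_len(n), function(i) {
    flags <- intersect(phrases$flag, names(rec))
    pos <- flags[vapply(flags, function(f) isTRUE(rec[[f]][i]), logical(1))]
    if (!length(pos)) return(NULL)
    data.frame(time = format(triage[i] - 86400, "%Y-%m-%dT%H:%M:%S"),
               text = phrases$phrase[match(pos, phrases$flag)],
               stringsAsFactors = FALSE)
  })

  getv <- function(f) if (f %in% names(rec)) rec[[f]] else rep(NA, n)
  visits <- visit_table(
    visit_id = sprintf("nhamcs-%06d", seq_len(n)),
    chief_complaint = cc,
    triage_time = triage,
    age = getv("age"), gender = getv("gender"), sbp = getv("sbp"),
    dbp = getv("dbp"), hr = getv("hr"), spo2 = getv("spo2"),
    rr = getv("rr"), bt = getv("bt"), pain = getv("pain"),
    gcs = getv("gcs"),
    icu_direct = !is.na(getv("icu_direct")) & getv("icu_direct"),
    hosp_death = !is.na(getv("hosp_death")) & getv("hosp_death"),
    history = hist)
  cl <- cleanse_visits(visits)
  list(visits = cl$kept, rejected = cl$rejected, excluded = excluded)
}
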