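# Visit-table model and preprocessing for emergency-department triage records.

#' Names of the 15 structural triage fields
#'
#' Order matters: it is the layout of the structural vector fed to the
#' embedding model (age, gender, systolic/diastolic blood pressure, heart
#' rate, SpO2, respiratory rate, body temperature, height, weight, pain
#' score, Glasgow coma scale total and its eye/verbal/motor components).
#'
#' @return Character vector of length 15.
#' @export
vital_fields <- function() {
  c("age", "gender", "sbp", "dbp", "hr", "spo2", "rr", "bt",
    "height", "weight", "pain", "gcs", "eye", "verbal", "motor")
}

.reject_reasons <- c("MISSING_CC", "SBP_GT_300", "DBP_GT_SBP", "HR_GT_250",
                     "RR_GT_100", "BT_OUT_OF_RANGE", "WT_GT_400", "HT_GT_250")

.as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
}

#' Construct a visit table
#'
#' Builds the canonical data frame of emergency-department visits used
#' throughout the package: one row per visit, the 15 structural fields as
#' columns (NA = missing), free-text chief complaint, a list-column of past
#' history records, and optional outcome timestamps/flags.
#'
#' @param visit_id character vector of unique visit identifiers.
#' @param chief_complaint character vector; empty or NA counts as missing.
#' @param ... named structural fields from [vital_fields()] plus optionally
#'   `patient_id`, `account_id`, `revisit_flag`, `triage_time`, `icu_time`,
#'   `death_time`, `icu_direct`, `hosp_death`. Unspecified vitals are NA.
#' @param history list of data frames with columns `time`, `text` (one per
#'   visit), or NULL for no histories.
#' @return A `data.frame` with one row per visit and a `history` list-column.
#' @export
visit_table <- function(visit_id, chief_complaint, ..., history = NULL) {
  n <- length(visit_id)
  extra <- list(...)
  df <- data.frame(visit_id = as.character(visit_id),
                   stringsAsFactors = FALSE)
  df$patient_id <- if (!is.null(extra$patient_id)) as.character(extra$patient_id) else df$visit_id
  df$account_id <- if (!is.null(extra$account_id)) as.character(extra$account_id) else df$visit_id
  df$revisit_flag <- if (!is.null(extra$revisit_flag)) as.integer(extra$revisit_flag) else 0L
  df$triage_time <- if (!is.null(extra$triage_time)) .as_time(extra$triage_time) else
    as.POSIXct(NA, tz = "UTC")
  df$chief_complaint <- as.character(chief_complaint)
  for (f in vital_fields()) {
    v <- extra[[f]]
    if (is.null(v)) v <- rep(NA, n)
    df[[f]] <- if (f == "gender") as.character(v) else as.numeric(v)
  }
  df$icu_time <- if (!is.null(extra$icu_time)) .as_time(extra$icu_time) else as.POSIXct(rep(NA, n), tz = "UTC")
  df$death_time <- if (!is.null(extra$death_time)) .as_time(extra$death_time) else as.POSIXct(rep(NA, n), tz = "UTC")
  df$icu_direct <- if (!is.null(extra$icu_direct)) as.logical(extra$icu_direct) else rep(NA, n)
  df$hosp_death <- if (!is.null(extra$hosp_death)) as.logical(extra$hosp_death) else rep(NA, n)
  if (is.null(history)) history <- rep(list(NULL), n)
  df$history <- history
  if (anyDuplicated(df$visit_id)) stop("visit_id values must be unique")
  df
}

#' Cleanse a visit table
#'
#' Applies the triage-record validity rules: a visit is rejected when its
#' chief complaint is missing/empty, or when any PRESENT structural field is
#' physiologically unreasonable (SBP > 300 mmHg, DBP > SBP, HR > 250 bpm,
#' RR > 100 breaths/min, body temperature outside 20-48 degrees C, weight >
#' 400 kg, height > 250 cm). Visits whose vitals are merely missing are
#' retained. Each rejection carries a machine-readable reason code (the
#' first rule violated, in the order above).
#'
#' @param visits a visit table (see [visit_table()]).
#' @return list with `kept` (visit table, input order preserved) and
#'   `rejected` (the rejected rows plus a `reason` column).
#' @export
cleanse_visits <- function(visits) {
  cc <- visits$chief_complaint
  bad <- list(
    MISSING_CC      = is.na(cc) | !nzchar(trimws(cc)),
    SBP_GT_300      = !is.na(visits$sbp) & visits$sbp > 300,
    DBP_GT_SBP      = !is.na(visits$dbp) & !is.na(visits$sbp) & visits$dbp > visits$sbp,
    HR_GT_250       = !is.na(visits$hr) & visits$hr > 250,
    RR_GT_100       = !is.na(visits$rr) & visits$rr > 100,
    BT_OUT_OF_RANGE = !is.na(visits$bt) & (visits$bt < 20 | visits$bt > 48),
    WT_GT_400       = !is.na(visits$weight) & visits$weight > 400,
    HT_GT_250       = !is.na(visits$height) & visits$height > 250
  )
  reason <- rep(NA_character_, nrow(visits))
  for (r in rev(names(bad))) reason[bad[[r]]] <- r
  rej <- !is.na(reason)
  rejected <- visits[rej, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[rej]
  else rejected$reason <- character(0)
  list(kept = visits[!rej, , drop = FALSE], rejected = rejected)
}

#' Deduplicate revisits within an account
#'
#' When a patient revisits under the same account, only the last record (the
#' maximal `revisit_flag`) is kept. The relative order of the retained
#' visits is preserved.
#'
#' @param visits a visit table.
#' @return The deduplicated visit table.
#' @export
deduplicate_revisits <- function(visits) {
  key <- paste(visits$account_id, visits$revisit_flag, sep = "\r")
  if (anyDuplicated(key)) stop("DUPLICATE_KEY: identical (account_id, revisit_flag) pairs")
  mx <- tapply(visits$revisit_flag, visits$account_id, max)
  keep <- visits$revisit_flag == as.numeric(mx[visits$account_id])
  visits[keep, , drop = FALSE]
}

#' Select pre-triage history records
#'
#' Filters a patient's past records to those strictly before the triage
#' time (future records must not leak into the input) and returns their
#' texts in chronological order.
#'
#' @param records data frame with columns `time`, `text` (or NULL).
#' @param triage_time the visit's triage timestamp.
#' @return Character vector of history texts (possibly empty).
#' @export
select_history <- function(records, triage_time) {
  if (is.null(records) || nrow(records) == 0L) return(character(0))
  tt <- .as_time(triage_time)
  tm <- .as_time(records$time)
  keep <- !is.na(tm) & tm < tt
  rec <- records[keep, , drop = FALSE]
  rec$text[order(.as_time(rec$time))]
}

#' Label the critical-care outcome
#'
#' The critical-care outcome is the union of ICU admission and death. In
#' `mode = "window"` the label is 1 when either event timestamp falls within
#' `window_days` days after triage (boundary inclusive). `mode = "nhamcs"`
#' instead uses the survey-style flags: direct ICU admission or in-hospital
#' death, with no time window.
#'
#' @param visits a visit table.
#' @param window_days length of the post-triage window in days (continuous
#'   time: 3 days = 72 hours).
#' @param mode "window" or "nhamcs".
#' @return Integer vector of 0/1 labels.
#' @export
label_critical_outcome <- function(visits, window_days = 3, mode = c("window", "nhamcs")) {
  mode <- match.arg(mode)
  if (mode == "nhamcs") {
    lab <- (!is.na(visits$icu_direct) & visits$icu_direct) |
           (!is.na(visits$hosp_death) & visits$hosp_death)
    return(as.integer(lab))
  }
  dicu <- as.numeric(difftime(visits$icu_time, visits$triage_time, units = "days"))
  ddth <- as.numeric(difftime(visits$death_time, visits$triage_time, units = "days"))
  hit <- function(d) !is.na(d) & d >= 0 & d <= window_days
  as.integer(hit(dicu) | hit(ddth))
}

.encode_gender <- function(g) {
  out <- rep(NA_real_, length(g))
  out[g %in% "male"] <- 1
  out[g %in% "female"] <- 0
  out
}

#' Extract the structural matrix from a visit table
#'
#' @param visits a visit table.
#' @return n x 15 numeric matrix (gender coded male = 1, female = 0; NA =
#'   missing), columns named by [vital_fields()].
#' @export
vitals_matrix <- function(visits) {
  m <- sapply(vital_fields(), function(f) {
    if (f == "gender") .encode_gender(visits$gender) else as.numeric(visits[[f]])
  })
  m <- matrix(m, nrow = nrow(visits), dimnames = list(visits$visit_id, vital_fields()))
  m
}

#' Per-field cohort statistics
#'
#' Means and standard deviations of every structural field, computed over
#' PRESENT values only (missing data are discarded before counting).
#'
#' @param visits a visit table (or a numeric matrix from [vitals_matrix()]).
#' @return data.frame with columns `field`, `mean`, `sd`.
#' @export
cohort_stats <- function(visits) {
  m <- if (is.matrix(visits)) visits else vitals_matrix(visits)
  data.frame(field = vital_fields(),
             mean = apply(m, 2L, mean, na.rm = TRUE),
             sd = apply(m, 2L, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

#' Impute missing vitals and add training-scale noise
#'
#' Missing fields are filled with the training means; when `noise_fraction >
#' 0`, each numeric element receives additive zero-mean Gaussian noise with
#' standard deviation `noise_fraction` times that field's training SD. The
#' gender code is categorical and is never perturbed. Deterministic given
#' the RNG state (set a seed before calling, or pass `seed`).
#'
#' @param vitals n x 15 matrix (or a visit table).
#' @param stats training-split statistics from [cohort_stats()].
#' @param noise_fraction non-negative noise scale in SD units.
#' @param seed optional integer; if given, a local seed is set.
#' @return n x 15 numeric matrix with no missing entries.
#' @export
impute_and_perturb <- function(vitals, stats, noise_fraction = 0, seed = NULL) {
  m <- if (is.matrix(vitals)) vitals else vitals_matrix(vitals)
  if (!all(vital_fields() %in% stats$field) ||
      any(is.na(stats$mean[match(vital_fields(), stats$field)])))
    stop("INCOMPLETE_STATS: stats must provide a mean for every field")
  mu <- stats$mean[match(colnames(m), stats$field)]
  sd <- stats$sd[match(colnames(m), stats$field)]
  sd[is.na(sd)] <- 0
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    m[miss, j] <- mu[j]
  }
  if (noise_fraction > 0) {
    noise <- matrix(stats::rnorm(length(m)), nrow(m)) *
      rep(noise_fraction * sd, each = nrow(m))
    noise[, colnames(m) == "gender"] <- 0
    m <- m + noise
  }
  m
}

#' Train/validation/test split sizes
#'
#' Rounding rule: `n_train` = round-half-up(`ratios[1]` * n), `n_test` =
#' round-half-up(`ratios[3]` * n), and `n_val` takes the remainder, so the
#' three sizes always sum to `n_total`.
#'
#' @param n_total number of visits.
#' @param ratios train/val/test fractions summing to 1.
#' @return list with `n_train`, `n_val`, `n_test`.
#' @export
split_sizes <- function(n_total, ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(n_total >= 0, abs(sum(ratios) - 1) < 1e-8)
  rhu <- function(x) floor(x + 0.5)
  n_train <- rhu(ratios[1] * n_total)
  n_test <- rhu(ratios[3] * n_total)
  list(n_train = n_train, n_val = n_total - n_train - n_test, n_test = n_test)
}

#' Assign visits to splits by seeded shuffle
#'
#' @param visit_ids character vector of visit identifiers.
#' @param seed integer seed for the shuffle.
#' @param ratios train/val/test fractions.
#' @return data.frame manifest with columns `visit_id`, `split`.
#' @export
assign_splits <- function(visit_ids, seed = 1L, ratios = c(0.8, 0.1, 0.1)) {
  sz <- split_sizes(length(visit_ids), ratios)
  set.seed(seed)
  perm <- sample(visit_ids)
  split <- rep(c("train", "val", "test"),
               times = c(sz$n_train, sz$n_val, sz$n_test))
  data.frame(visit_id = perm, split = split, stringsAsFactors = FALSE)
}

# ---- file I/O --------------------------------------------------------------

.time_str <- function(x) ifelse(is.na(x), NA_character_,
                                format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))

#' Write a visit table as JSONL
#'
#' One JSON object per line; timestamps as ISO-8601 strings, missing values
#' as nulls, histories as arrays of `{time, text}`.
#'
#' @param visits a visit table.
#' @param path output file path.
#' @export
write_visits_jsonl <- function(visits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(visits))) {
    row <- visits[i, ]
    h <- row$history[[1]]
    obj <- list(visit_id = row$visit_id, patient_id = row$patient_id,
                account_id = row$account_id, revisit_flag = row$revisit_flag,
                triage_time = .time_str(row$triage_time),
                chief_complaint = row$chief_complaint,
                history = if (is.null(h) || nrow(h) == 0L) list() else
                  lapply(seq_len(nrow(h)), function(k)
                    list(time = .time_str(.as_time(h$time[k])), text = h$text[k])),
                icu_time = .time_str(row$icu_time),
                death_time = .time_str(row$death_time),
                icu_direct = row$icu_direct, hosp_death = row$hosp_death)
    for (f in vital_fields()) obj[[f]] <- if (f == "gender") row$gender else row[[f]]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                na = "null", digits = NA), con)
  }
  invisible(path)
}

#' Read a JSONL visit table
#'
#' @param path file written by [write_visits_jsonl()].
#' @return a visit table.
#' @export
read_visits_jsonl <- function(path) {
  lines <- readLines(path)
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  pick <- function(f, as = as.character) as(sapply(objs, function(o)
    if (is.null(o[[f]]) || length(o[[f]]) == 0L) NA else o[[f]]))
  hist <- lapply(objs, function(o) {
    h <- o$history
    if (is.null(h) || length(h) == 0L) return(NULL)
    data.frame(time = h$time, text = h$text, stringsAsFactors = FALSE)
  })
  args <- list(visit_id = pick("visit_id"),
               chief_complaint = pick("chief_complaint"),
               patient_id = pick("patient_id"), account_id = pick("account_id"),
               revisit_flag = pick("revisit_flag", as.integer),
               triage_time = pick("triage_time"),
               icu_time = pick("icu_time"), death_time = pick("death_time"),
               icu_direct = pick("icu_direct", as.logical),
               hosp_death = pick("hosp_death", as.logical),
               history = hist)
  for (f in vital_fields())
    args[[f]] <- if (f == "gender") pick("gender") else pick(f, as.numeric)
  do.call(visit_table, args)
}
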