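#' Clinical seizure-recognition scoring
#'
#' During monitoring the bedside team completes an hourly seizure record
#' form, and antiseizure medication (ASM) administrations are logged. The
#' trial's recognition rules, all at hour granularity, are:
#'
#' * Neonate level: the team identified the neonate as having seizures if at
#'   least one hour was marked on the form or at least one therapeutic ASM
#'   dose was given.
#' * Hour level: a gold seizure hour H was identified if the form was marked
#'   or ASM was given in H or in H+1 (the hour after).
#' * A form-marked hour H is a false detection if no confirmed seizure
#'   occurred in H or in H-1 (the hour before).
#' * An ASM given at hour H is inappropriate if no confirmed seizure
#'   occurred in H or in H-1.
#'
#' Hour records are data frames with columns `hour_index` (0-based),
#' `form_marked`, `asm_given` (logical or 0/1) and optionally
#' `asm_therapeutic` (default 1: the dose counts towards identification).
#'
#' @name clinical-scoring
NULL

as_hours <- function(hours, n_hours = NULL) {
  stopifnot(all(c("hour_index", "form_marked", "asm_given") %in% names(hours)))
  hi <- as.integer(hours$hour_index)
  if (anyDuplicated(hi)) {
    stop("duplicate hour_index in clinical record", call. = FALSE)
  }
  n <- n_hours %||% if (length(hi) == 0) 0L else max(hi) + 1L
  n <- as.integer(n)
  if (length(hi) < n) {
    warning(sprintf("%d missing hour row(s) treated as blank",
                    n - length(hi)), call. = FALSE)
  }
  form <- logical(n)
  asm <- logical(n)
  keep <- hi < n
  form[hi[keep] + 1L] <- as.logical(hours$form_marked)[keep]
  asm[hi[keep] + 1L] <- as.logical(hours$asm_given)[keep] &
    (as.logical(hours[["asm_therapeutic"]] %||% rep(TRUE, length(hi)))[keep])
  fast_tb(hour_index = seq_len(n) - 1L, form_marked = form, asm_given = asm)
}

#' Neonate-level clinical classification
#'
#' @param hours hour-record data frame for one neonate.
#' @return `TRUE` iff any hour has a form mark or a therapeutic ASM dose.
#' @export
classify_neonate_clinical <- function(hours) {
  h <- as_hours(hours)
  any(h$form_marked | h$asm_given)
}

#' Score every hour of one neonate's record
#'
#' Applies the hour-level identification and false-detection rules against
#' the gold seizure hours.
#'
#' @param hours hour-record data frame for one neonate.
#' @param gold_hours integer vector of confirmed seizure-hour indices.
#' @param n_hours total number of hour bins in the recording (missing rows
#'   are treated as blank up to this count).
#' @return tibble with one row per hour: `hour_index`, `form_marked`,
#'   `asm_given`, `gold_seizure_hour`, `identified` (`NA` for non-gold
#'   hours), `false_detection`.
#' @export
score_hours <- function(hours, gold_hours, n_hours = NULL) {
  h <- as_hours(hours, n_hours = n_hours)
  n <- nrow(h)
  if (n == 0) {
    return(tibble::tibble(
      hour_index = integer(0), form_marked = logical(0),
      asm_given = logical(0), gold_seizure_hour = logical(0),
      identified = logical(0), false_detection = logical(0)
    ))
  }
  gold <- h$hour_index %in% gold_hours
  flag <- h$form_marked | h$asm_given
  flag_next <- c(flag[-1], FALSE)          # H+1 beyond the record is nothing
  gold_prev <- c(FALSE, gold[-n])          # H-1 clause skipped at H = 0
  identified <- flag | flag_next
  identified[!gold] <- NA
  fast_tb(
    hour_index = h$hour_index,
    form_marked = h$form_marked,
    asm_given = h$asm_given,
    gold_seizure_hour = gold,
    identified = identified,
    false_detection = h$form_marked & !gold & !gold_prev
  )
}

#' Inappropriate antiseizure-medication administrations
#'
#' An ASM dose at hour H is inappropriate iff there was no confirmed seizure
#' in H or H-1 (the hour before allows for preparation and administration
#' time).
#'
#' @inheritParams score_hours
#' @return list: `n_inappropriate` (count of inappropriate administrations)
#'   and `any_inappropriate` (logical).
#' @export
inappropriate_asm <- function(hours, gold_hours, n_hours = NULL) {
  h <- as_hours(hours, n_hours = n_hours)
  gold <- h$hour_index %in% gold_hours
  gold_prev <- c(FALSE, gold[-length(gold)])
  if (nrow(h) == 0) gold_prev <- logical(0)
  inapp <- h$asm_given & !gold & !gold_prev
  list(n_inappropriate = sum(inapp), any_inappropriate = any(inapp))
}

#' Neonate-level confusion counts
#'
#' Crosses the gold-standard seizure status (at least one confirmed event)
#' with the clinical classification for a set of neonates.
#'
#' @param status data frame with one row per neonate: `neonate_id`,
#'   `gold_positive` (logical), `clinical_positive` (logical).
#' @param allow_duplicates permit repeated neonates (`TRUE` inside bootstrap
#'   resamples, where neonates recur by design; `FALSE` for observed
#'   cohorts, where a repeated id is an input error).
#' @return named list `tp`, `tn`, `fp`, `fn`.
#' @export
neonate_confusion <- function(status, allow_duplicates = FALSE) {
  if (!allow_duplicates && anyDuplicated(status$neonate_id)) {
    stop("duplicate neonate_id in cohort", call. = FALSE)
  }
  g <- as.logical(status$gold_positive)
  p <- as.logical(status$clinical_positive)
  list(tp = sum(g & p), tn = sum(!g & !p), fp = sum(!g & p), fn = sum(g & !p))
}

#' Aggregate hour-level detection counts
#'
#' Summarises scored hours (from [score_hours()], possibly concatenated over
#' many neonates) into the four counts used by the hour-level accuracy
#' metrics. The false-detection denominator counts form-marked hours only:
#' medication-only events contribute to identification but not to this
#' denominator.
#'
#' @param scores tibble of scored hours.
#' @return one-row tibble: `n_gold_hours`, `n_identified`, `n_marked_hours`,
#'   `n_false_detections`.
#' @export
hour_detection_summary <- function(scores) {
  tibble::tibble(
    n_gold_hours = sum(scores$gold_seizure_hour),
    n_identified = sum(scores$identified[scores$gold_seizure_hour]),
    n_marked_hours = sum(scores$form_marked),
    n_false_detections = sum(scores$false_detection)
  )
}

#' Calendar strata for each recorded hour
#'
#' Assigns each hour bin to a day-of-week stratum (weekday Mon-Fri vs
#' weekend Sat-Sun) and a shift stratum (day shift 0800-2000 h vs night
#' shift 2000-0800 h), by the wall-clock instant at which the bin starts.
#'
#' @param start_datetime POSIXct (or ISO-8601 string) recording start.
#' @param n_hours number of hour bins.
#' @return tibble: `hour_index`, `day_type` ("weekday"/"weekend"), `shift`
#'   ("day"/"night").
#' @export
hour_strata <- function(start_datetime, n_hours) {
  if (is.character(start_datetime)) {
    start_datetime <- as.POSIXct(start_datetime,
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  if (is.na(start_datetime)) {
    stop("a recording start timestamp is required for stratification",
         call. = FALSE)
  }
  t <- start_datetime + 3600 * (seq_len(n_hours) - 1)
  lt <- as.POSIXlt(t, tz = "UTC")
  hod <- lt$hour + lt$min / 60
  fast_tb(
    hour_index = seq_len(n_hours) - 1L,
    day_type = ifelse(lt$wday %in% c(0, 6), "weekend", "weekday"),
    shift = ifelse(hod >= 8 & hod < 20, "day", "night")
  )
}

#' Score a whole cohort at neonate and hour level
#'
#' Runs [score_hours()] and [inappropriate_asm()] for every neonate and
#' attaches calendar strata when start timestamps are available.
#'
#' @param clinical data frame: `neonate_id`, `hour_index`, `form_marked`,
#'   `asm_given`, optionally `asm_therapeutic`.
#' @param consensus named list from [build_consensus()].
#' @param metadata data frame: `neonate_id`, `hospital`, `group`,
#'   `recording_duration_h`, optionally `start_datetime`.
#' @return list with `hour_scores` (tibble over all neonates, with `group`,
#'   `hospital`, and — when timestamps exist — `day_type`/`shift`) and
#'   `neonates` (one row per neonate: gold/clinical status, per-neonate hour
#'   counts, inappropriate-ASM count and flag).
#' @export
score_cohort <- function(clinical, consensus, metadata) {
  scores <- list()
  neonates <- list()
  has_ts <- "start_datetime" %in% names(metadata)
  clin_rows <- split(seq_len(nrow(clinical)), clinical$neonate_id)
  for (i in seq_len(nrow(metadata))) {
    id <- metadata$neonate_id[i]
    cons <- consensus[[as.character(id)]]
    if (is.null(cons)) {
      stop(sprintf("no consensus annotation for neonate %s", id),
           call. = FALSE)
    }
    n_hours <- max(1L, ceiling(cons$recording_duration_h - 1e-9))
    hrs <- clinical[clin_rows[[as.character(id)]] %||% integer(0), ]
    gold <- seizure_hours(cons)
    sc <- score_hours(hrs, gold, n_hours = n_hours)
    sc$neonate_id <- rep(id, nrow(sc))
    sc$group <- rep(metadata$group[i], nrow(sc))
    sc$hospital <- rep(metadata$hospital[i], nrow(sc))
    if (has_ts && !is.na(metadata$start_datetime[i])) {
      st <- hour_strata(metadata$start_datetime[i], n_hours)
      sc$day_type <- st$day_type[match(sc$hour_index, st$hour_index)]
      sc$shift <- st$shift[match(sc$hour_index, st$hour_index)]
    }
    asm <- inappropriate_asm(hrs, gold, n_hours = n_hours)
    scores[[i]] <- sc
    neonates[[i]] <- fast_tb(
      neonate_id = id,
      group = metadata$group[i],
      hospital = metadata$hospital[i],
      gold_positive = is_seizure_neonate(cons),
      clinical_positive = classify_neonate_clinical(hrs),
      n_gold_hours = sum(sc$gold_seizure_hour),
      n_identified = sum(sc$identified[sc$gold_seizure_hour]),
      n_marked_hours = sum(sc$form_marked),
      n_false_detections = sum(sc$false_detection),
      n_inappropriate_asm = asm$n_inappropriate,
      any_inappropriate_asm = asm$any_inappropriate
    )
  }
  list(
    hour_scores = dplyr::bind_rows(scores),
    neonates = dplyr::bind_rows(neonates)
  )
}
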