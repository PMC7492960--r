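#' Interval algebra for expert seizure annotations
#'
#' Seizure annotations are lists of `[start_s, end_s)` intervals in seconds
#' from recording start. The consensus gold standard is built from the
#' set-intersection of two independent expert annotations: only periods where
#' both experts marked a seizure count, and an intersection segment is
#' confirmed as an electrographic seizure when it lasts at least 30 s
#' (expert agreement on events shorter than 30 s is known to be poor, which
#' is why the confirmation threshold sits above the 10 s electrographic
#' seizure definition).
#'
#' All functions work on data frames with numeric columns `start_s` and
#' `end_s`. Arithmetic is floating point with a 1 ms tolerance: segments
#' that touch or overlap within `tol` are merged, and degenerate segments
#' shorter than `tol` are discarded.
#'
#' @name interval-algebra
NULL

INTERVAL_TOL <- 1e-3

as_events <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(fast_tb(start_s = numeric(0), end_s = numeric(0)))
  }
  stopifnot(is.data.frame(x), all(c("start_s", "end_s") %in% names(x)))
  fast_tb(start_s = as.numeric(x$start_s), end_s = as.numeric(x$end_s))
}

#' Normalise an annotation set
#'
#' Sorts events by start time and merges overlapping or touching events into
#' maximal disjoint intervals, preserving total covered time. This is the
#' canonical form required by [intersect_events()].
#'
#' @param events data frame with `start_s`, `end_s` columns (seconds).
#' @param tol merge tolerance in seconds; events whose gap is below `tol`
#'   are treated as touching.
#' @return tibble of disjoint events sorted by `start_s`.
#' @export
#' @examples
#' normalize_events(data.frame(start_s = c(0, 40), end_s = c(50, 90)))
normalize_events <- function(events, tol = INTERVAL_TOL) {
  ev <- as_events(events)
  bad <- which(!(ev$end_s > ev$start_s))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid interval at row %d: end_s (%g) must exceed start_s (%g)",
      bad[1], ev$end_s[bad[1]], ev$start_s[bad[1]]
    ), call. = FALSE)
  }
  if (nrow(ev) == 0) return(ev)
  ev <- ev[order(ev$start_s, ev$end_s), ]
  start <- ev$start_s[1]
  end <- ev$end_s[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$start_s[i] <= end + tol) {
        end <- max(end, ev$end_s[i])
      } else {
        out_s <- c(out_s, start)
        out_e <- c(out_e, end)
        start <- ev$start_s[i]
        end <- ev$end_s[i]
      }
    }
  }
  fast_tb(start_s = c(out_s, start), end_s = c(out_e, end))
}

#' Intersect two normalised annotation sets
#'
#' Returns the set-intersection of the two interval unions as maximal
#' disjoint segments, sorted by start. These are the periods during which
#' both experts annotated a seizure; they form the final annotation once
#' passed through [confirm_events()].
#'
#' @param a,b normalised event data frames (see [normalize_events()]).
#' @param tol tolerance in seconds; intersection segments shorter than `tol`
#'   are dropped as degenerate.
#' @return tibble of disjoint intersection segments.
#' @export
intersect_events <- function(a, b, tol = INTERVAL_TOL) {
  a <- as_events(a)
  b <- as_events(b)
  empty <- fast_tb(start_s = numeric(0), end_s = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  i <- 1L
  j <- 1L
  out_s <- numeric(0)
  out_e <- numeric(0)
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a$start_s[i], b$start_s[j])
    hi <- min(a$end_s[i], b$end_s[j])
    if (hi - lo > tol) {
      out_s <- c(out_s, lo)
      out_e <- c(out_e, hi)
    }
    if (a$end_s[i] < b$end_s[j]) i <- i + 1L else j <- j + 1L
  }
  fast_tb(start_s = out_s, end_s = out_e)
}

#' Confirm electrographic seizures from intersection segments
#'
#' Keeps exactly the intersection segments whose duration is at least
#' `min_overlap_s` (inclusive, with the 1 ms floating-point tolerance). The
#' retained segments are the confirmed seizure events, i.e. the gold
#' standard.
#'
#' @param segments disjoint sorted segments from [intersect_events()].
#' @param min_overlap_s minimum dual-annotation overlap in seconds
#'   (default 30).
#' @param tol tolerance in seconds for the boundary comparison.
#' @return tibble of confirmed events.
#' @export
confirm_events <- function(segments, min_overlap_s = 30, tol = INTERVAL_TOL) {
  if (min_overlap_s < 0) {
    stop("min_overlap_s must be non-negative", call. = FALSE)
  }
  seg <- as_events(segments)
  seg[seg$end_s - seg$start_s >= min_overlap_s - tol, ]
}

#' Build the consensus annotation for one neonate
#'
#' Full dual-expert consensus: normalise each annotator's events, intersect,
#' and confirm segments of at least `min_overlap_s`.
#'
#' @param a,b event data frames, one per annotator.
#' @param recording_duration_h recording duration in hours (positive).
#' @param min_overlap_s confirmation threshold in seconds.
#' @return list of class `consensus_annotation` with elements `events`
#'   (confirmed events tibble) and `recording_duration_h`.
#' @export
consensus_annotation <- function(a, b, recording_duration_h,
                                 min_overlap_s = 30) {
  stopifnot(is.numeric(recording_duration_h), recording_duration_h > 0)
  ev <- confirm_events(
    intersect_events(normalize_events(a), normalize_events(b)),
    min_overlap_s = min_overlap_s
  )
  structure(
    list(events = ev, recording_duration_h = recording_duration_h),
    class = "consensus_annotation"
  )
}

#' Is this a seizure neonate?
#'
#' A neonate is a seizure neonate iff at least one confirmed event exists
#' (dual-annotation overlap of at least 30 s).
#'
#' @param c a `consensus_annotation`.
#' @return logical scalar.
#' @export
is_seizure_neonate <- function(c) {
  nrow(c$events) > 0
}

clip_events <- function(events, duration_s) {
  ev <- as_events(events)
  if (any(ev$end_s > duration_s + INTERVAL_TOL)) {
    warning("confirmed event extends beyond recording duration; clipped",
            call. = FALSE)
  }
  ev$end_s <- pmin(ev$end_s, duration_s)
  ev$start_s <- pmin(ev$start_s, duration_s)
  ev[ev$end_s - ev$start_s > INTERVAL_TOL, ]
}

#' Per-hour seizure burden
#'
#' Hour bins are consecutive 60 min windows `[3600k, 3600(k+1))` anchored at
#' recording start (bin index 0); `offset_s` shifts the bin grid for
#' wall-clock alignment when needed. The final partial hour is a valid bin;
#' burden in it is the actual overlap (no rescaling to a full hour).
#'
#' @param c a `consensus_annotation`.
#' @param offset_s bin-grid offset in seconds (default 0, recording-anchored).
#' @return numeric vector of burden minutes per hour bin, length
#'   `ceiling(recording_duration_h)`.
#' @export
hourly_burden <- function(c, offset_s = 0) {
  duration_s <- c$recording_duration_h * 3600
  n_bins <- max(1L, ceiling(c$recording_duration_h - 1e-9))
  out <- numeric(n_bins)
  ev <- clip_events(c$events, duration_s)
  if (nrow(ev) == 0) return(out)
  for (i in seq_len(nrow(ev))) {
    k0 <- max(0L, floor((ev$start_s[i] - offset_s) / 3600))
    k1 <- min(n_bins - 1L, floor((ev$end_s[i] - offset_s - 1e-9) / 3600))
    for (k in k0:k1) {
      lo <- max(ev$start_s[i], offset_s + 3600 * k)
      hi <- min(ev$end_s[i], offset_s + 3600 * (k + 1))
      if (hi > lo) out[k + 1L] <- out[k + 1L] + (hi - lo) / 60
    }
  }
  out
}

#' Confirmed seizure hours
#'
#' Hour bin `k` is a seizure hour iff some confirmed event overlaps it with
#' positive duration (beyond the 1 ms tolerance). A seizure spanning an hour
#' boundary counts in both hours.
#'
#' @inheritParams hourly_burden
#' @return integer vector of 0-based hour indices, sorted.
#' @export
seizure_hours <- function(c, offset_s = 0) {
  b <- hourly_burden(c, offset_s = offset_s)
  which(b * 60 > INTERVAL_TOL) - 1L
}

#' Seizure-burden summary for one neonate
#'
#' Computes the three standard burden summaries over the confirmed (final)
#' annotation: total seizure burden in minutes (accumulated confirmed
#' seizure duration over the whole recording), maximum hourly burden in
#' min/h (the hour bin with the most seizure activity), and median confirmed
#' event duration in seconds (`NA` when there are no confirmed events).
#'
#' @inheritParams hourly_burden
#' @return one-row tibble: `total_burden_min`, `max_hourly_burden_min_per_h`,
#'   `median_duration_s`, `n_events`.
#' @export
burden_summary <- function(c, offset_s = 0) {
  ev <- clip_events(c$events, c$recording_duration_h * 3600)
  durs <- ev$end_s - ev$start_s
  tibble::tibble(
    total_burden_min = sum(durs) / 60,
    max_hourly_burden_min_per_h =
      if (nrow(ev) == 0) 0 else max(hourly_burden(c, offset_s = offset_s)),
    median_duration_s = if (nrow(ev) == 0) NA_real_ else stats::median(durs),
    n_events = nrow(ev)
  )
}

#' Consensus annotations for a whole cohort
#'
#' Pairs the two annotators' event sets per neonate and applies the
#' consensus rule. Exactly two annotator ids must be present across the
#' annotation table; a neonate with no rows for an annotator is treated as
#' an empty annotation from that annotator.
#'
#' @param annotations data frame: `neonate_id`, `annotator_id`, `start_s`,
#'   `end_s` (one row per raw expert event).
#' @param metadata data frame with `neonate_id` and `recording_duration_h`.
#' @param min_overlap_s confirmation threshold in seconds.
#' @return named list of `consensus_annotation`, one per metadata neonate.
#' @export
build_consensus <- function(annotations, metadata, min_overlap_s = 30) {
  anns <- unique(annotations$annotator_id)
  if (length(anns) != 2) {
    stop(sprintf(
      "exactly two annotators are required; found %d (%s)",
      length(anns), paste(anns, collapse = ", ")
    ), call. = FALSE)
  }
  extra <- setdiff(unique(annotations$neonate_id), metadata$neonate_id)
  if (length(extra) > 0) {
    stop(sprintf(
      "neonate(s) present in annotations but absent from metadata: %s",
      paste(utils::head(extra, 5), collapse = ", ")
    ), call. = FALSE)
  }
  ann_rows <- split(seq_len(nrow(annotations)), annotations$neonate_id)
  out <- lapply(seq_len(nrow(metadata)), function(i) {
    id <- metadata$neonate_id[i]
    rows <- annotations[ann_rows[[as.character(id)]] %||% integer(0), ]
    consensus_annotation(
      rows[rows$annotator_id == anns[1], c("start_s", "end_s")],
      rows[rows$annotator_id == anns[2], c("start_s", "end_s")],
      recording_duration_h = metadata$recording_duration_h[i],
      min_overlap_s = min_overlap_s
    )
  })
  names(out) <- metadata$neonate_id
  out
}

#' Tabulate confirmed events across a cohort
#'
#' @param consensus named list from [build_consensus()].
#' @return tibble: `neonate_id`, `event_index`, `start_s`, `end_s`,
#'   `duration_s`.
#' @export
consensus_table <- function(consensus) {
  rows <- lapply(names(consensus), function(id) {
    ev <- consensus[[id]]$events
    if (nrow(ev) == 0) return(NULL)
    tibble::tibble(
      neonate_id = id,
      event_index = seq_len(nrow(ev)),
      start_s = ev$start_s,
      end_s = ev$end_s,
      duration_s = ev$end_s - ev$start_s
    )
  })
  dplyr::bind_rows(rows)
}

#' Burden summaries across a cohort
#'
#' @param consensus named list from [build_consensus()].
#' @return tibble with one row per neonate: `neonate_id`, the three burden
#'   summaries and `n_events`.
#' @export
burden_table <- function(consensus) {
  dplyr::bind_rows(lapply(names(consensus), function(id) {
    dplyr::bind_cols(tibble::tibble(neonate_id = id),
                     burden_summary(consensus[[id]]))
  }))
}
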