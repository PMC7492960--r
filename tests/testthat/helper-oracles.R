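# Brute-force oracles, independent of the package's interval algebra.
# They only handle integer-endpoint events, representing coverage as the
# set of whole seconds [s, s+1) contained in any event.

sec_cover <- function(events) {
  if (nrow(events) == 0) return(integer(0))
  sort(unique(unlist(mapply(
    function(s, e) if (e > s) seq.int(s, e - 1L) else integer(0),
    as.integer(events$start_s), as.integer(events$end_s), SIMPLIFY = FALSE
  ))))
}

# contiguous runs of covered seconds -> intervals (end exclusive)
secs_to_intervals <- function(secs) {
  if (length(secs) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  brk <- which(diff(secs) > 1)
  starts <- secs[c(1, brk + 1)]
  ends <- secs[c(brk, length(secs))] + 1L
  data.frame(start_s = as.numeric(starts), end_s = as.numeric(ends))
}

# random possibly-overlapping integer event set within [0, tmax]
rand_events <- function(n, tmax = 4 * 3600, min_len = 1, max_len = 900) {
  len <- sample.int(max_len - min_len + 1L, n, replace = TRUE) + min_len - 1L
  start <- sample.int(tmax - max_len, n, replace = TRUE)
  data.frame(start_s = as.numeric(start), end_s = as.numeric(start + len))
}

# Rule-table oracle for one neonate's hour-level scoring, written as direct
# per-hour loops over the trial's stated rules.
score_oracle <- function(gold, marks, asms, n_hours) {
  identified <- rep(NA, n_hours)
  false_det <- rep(FALSE, n_hours)
  inappropriate <- rep(FALSE, n_hours)
  for (h in seq_len(n_hours) - 1L) {
    flag_h <- (h %in% marks) || (h %in% asms)
    flag_next <- ((h + 1) < n_hours) && ((h + 1) %in% marks || (h + 1) %in% asms)
    if (h %in% gold) identified[h + 1] <- flag_h || flag_next
    if (h %in% marks) {
      false_det[h + 1] <- !(h %in% gold) && !(h >= 1 && (h - 1) %in% gold)
    }
    if (h %in% asms) {
      inappropriate[h + 1] <- !(h %in% gold) && !(h >= 1 && (h - 1) %in% gold)
    }
  }
  list(identified = identified, false_detection = false_det,
       inappropriate = inappropriate)
}

hours_df <- function(n_hours, marks = integer(0), asms = integer(0)) {
  data.frame(
    hour_index = seq_len(n_hours) - 1L,
    form_marked = as.integer((seq_len(n_hours) - 1L) %in% marks),
    asm_given = as.integer((seq_len(n_hours) - 1L) %in% asms)
  )
}

# Build a minimal one-neonate cohort slice for pipeline-level fixtures:
# a seizure neonate has one 60 s confirmed event in hour 0.
fixture_neonate <- function(id, group, hospital, gold, clinical_mark,
                            duration_h = 4) {
  ann <- if (gold) {
    data.frame(neonate_id = id, annotator_id = rep(c("E1", "E2"), each = 1),
               start_s = 100, end_s = 160)
  } else {
    NULL
  }
  clin <- data.frame(
    neonate_id = id, hour_index = 0:(duration_h - 1),
    form_marked = 0L, asm_given = 0L
  )
  if (clinical_mark) clin$form_marked[1] <- 1L
  meta <- data.frame(neonate_id = id, hospital = hospital, group = group,
                     recording_duration_h = duration_h)
  list(annotations = ann, clinical = clin, metadata = meta)
}

# Assemble a cohort with exact confusion counts per group; every annotation
# table keeps both annotator ids present (required by the consensus rule).
fixture_cohort <- function(counts_by_group, n_hospitals = 8) {
  anns <- list(); clins <- list(); metas <- list()
  idx <- 0
  for (g in names(counts_by_group)) {
    cc <- counts_by_group[[g]]
    plan <- rbind(
      data.frame(gold = TRUE, mark = TRUE)[rep(1, cc["tp"]), , drop = FALSE],
      data.frame(gold = FALSE, mark = FALSE)[rep(1, cc["tn"]), , drop = FALSE],
      data.frame(gold = FALSE, mark = TRUE)[rep(1, cc["fp"]), , drop = FALSE],
      data.frame(gold = TRUE, mark = FALSE)[rep(1, cc["fn"]), , drop = FALSE]
    )
    for (r in seq_len(nrow(plan))) {
      idx <- idx + 1
      fx <- fixture_neonate(sprintf("P%04d", idx), g,
                            sprintf("H%d", (idx %% n_hospitals) + 1),
                            plan$gold[r], plan$mark[r])
      anns[[idx]] <- fx$annotations
      clins[[idx]] <- fx$clinical
      metas[[idx]] <- fx$metadata
    }
  }
  ann <- do.call(rbind, anns[!vapply(anns, is.null, logical(1))])
  list(annotations = ann,
       clinical = do.call(rbind, clins),
       metadata = do.call(rbind, metas))
}
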