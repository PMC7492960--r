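#' Synthetic trial cohort configuration
#'
#' Parameters of the synthetic two-arm cohort generator. Defaults emulate
#' the published marginals of a multicentre neonatal seizure-recognition
#' trial: two arms of 130 neonates across 8 hospitals, seizure prevalence
#' 25% / 29%, log-normal monitoring durations with median about 50 h,
#' seizure-event trains whose totals match the reported burden summaries
#' (median total burden in the tens of minutes, median event duration about
#' 105 s, maximum hourly burden around 13 min/h), two imperfect annotators,
#' and a burden-dependent logistic model of bedside hour-level recognition.
#'
#' @param n_per_group neonates per randomisation group.
#' @param n_hospitals number of recruiting hospitals (clusters are
#'   group x hospital).
#' @param prevalence named per-group probability that a neonate has
#'   electrographic seizures.
#' @param duration log-normal parameters (h) of monitoring duration, clamped
#'   to `[min_h, max_h]`.
#' @param events seizure-train model for a seizure neonate: `n_mu`/`n_size`
#'   (negative-binomial event count, shifted to be at least 1), log-normal
#'   event duration (s) clamped to `[dur_min_s, dur_max_s]`, exponential
#'   within-bout gaps (`gap_mean_s`), Poisson bout splitting
#'   (`bout_rate`, bouts per 8 events) and exponential inter-bout gaps
#'   (`interbout_mean_s`).
#' @param annotators boundary jitter SD (s), miss probability for events
#'   shorter than `miss_below_s`, and spurious short-event rate per hour.
#' @param detection hour-level recognition model: per-group intercept and
#'   common slope of `logit P(mark gold hour) ~ log(hourly burden, min)`,
#'   a weekend log-odds offset, and the false-mark model. False marks are
#'   concentrated in neonates under raised clinical suspicion (probability
#'   `p_suspected` by seizure status), who accrue form marks on
#'   non-seizure hours at `false_mark_rate["suspected"]` per hour;
#'   everyone else only at the `background` rate. ASM follows marks (`p_asm_true_mark` when the mark
#'   sits on or just after a confirmed seizure hour, `p_asm_false_mark`
#'   otherwise) plus a small background ASM rate per hour, which is what
#'   produces inappropriate administrations.
#' @param start_window first day and span (days) of the uniform recording
#'   start-time window.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_group = 130,
    n_hospitals = 8,
    prevalence = c(algorithm = 0.25, non_algorithm = 0.29),
    duration = list(meanlog = log(50), sdlog = 0.85, min_h = 2, max_h = 100),
    events = list(n_mu = 20, n_size = 2, dur_meanlog = log(105),
                  dur_sdlog = 0.8, dur_min_s = 10, dur_max_s = 1800,
                  gap_mean_s = 240, bout_rate = 1 / 8,
                  interbout_mean_s = 7200),
    annotators = list(jitter_sd_s = 5, miss_prob_short = 0.15,
                      miss_below_s = 60, spurious_rate_per_h = 0.03,
                      spurious_dur_s = c(10, 40)),
    detection = list(
      intercepts = c(algorithm = -2.0011, non_algorithm = -2.9555),
      slope = 1.1, weekend_lor = -0.4,
      p_suspected = c(seizure = 0.5, non_seizure = 0.15),
      false_mark_rate = c(suspected = 0.08, background = 0.001),
      p_asm_true_mark = 0.5, p_asm_false_mark = 0.2,
      asm_background_rate = 0.001),
    start_window = list(origin = "2015-02-01", span_days = 365),
    seed = 1) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1),
            all(unlist(detection[c("false_mark_rate", "p_asm_true_mark",
                                   "p_asm_false_mark",
                                   "asm_background_rate")]) >= 0))
  structure(
    list(n_per_group = n_per_group, n_hospitals = n_hospitals,
         prevalence = prevalence, duration = duration, events = events,
         annotators = annotators, detection = detection,
         start_window = start_window, seed = seed, planted = NULL),
    class = "cohort_config"
  )
}

# Draw one seizure-event train for a seizure neonate; retries until at least
# one event of >= 30 s survives within the recording (so every intended
# seizure neonate is confirmable under faithful annotation).
gen_event_train <- function(duration_h, ev) {
  dur_s <- duration_h * 3600
  for (try in 1:25) {
    n_ev <- 1 + stats::rnbinom(1, mu = ev$n_mu - 1, size = ev$n_size)
    durs <- pmin(ev$dur_max_s,
                 pmax(ev$dur_min_s,
                      stats::rlnorm(n_ev, ev$dur_meanlog, ev$dur_sdlog)))
    n_bouts <- 1 + stats::rpois(1, n_ev * ev$bout_rate)
    bout <- sort(sample.int(n_bouts, n_ev, replace = TRUE))
    new_bout <- if (n_ev == 1) TRUE else c(TRUE, bout[-1] != bout[-n_ev])
    gaps <- ifelse(new_bout,
                   600 + stats::rexp(n_ev, 1 / ev$interbout_mean_s),
                   30 + stats::rexp(n_ev, 1 / ev$gap_mean_s))
    gaps[1] <- 0
    starts <- cumsum(gaps) + cumsum(c(0, durs[-n_ev]))
    span <- starts[n_ev] + durs[n_ev]
    offset <- if (span < dur_s) stats::runif(1, 0, dur_s - span) else 0
    s <- starts + offset
    e <- s + durs
    keep <- s < dur_s - 10
    s <- s[keep]
    e <- pmin(e[keep], dur_s)
    keep2 <- (e - s) >= 10
    out <- fast_tb(start_s = s[keep2], end_s = e[keep2])
    if (any(out$end_s - out$start_s >= 30)) return(out)
  }
  # extremely short recordings: fall back to one guaranteed event
  fast_tb(start_s = 0, end_s = min(dur_s, 120))
}

# One annotator's reading of the true events: boundary jitter, misses of
# short events, spurious short events, then normalisation.
annotate_events <- function(true_events, duration_h, an) {
  dur_s <- duration_h * 3600
  ev <- true_events
  if (nrow(ev) > 0) {
    short <- (ev$end_s - ev$start_s) < an$miss_below_s
    missed <- short & (stats::runif(nrow(ev)) < an$miss_prob_short)
    ev <- ev[!missed, , drop = FALSE]
  }
  if (nrow(ev) > 0 && an$jitter_sd_s > 0) {
    s <- ev$start_s + stats::rnorm(nrow(ev), 0, an$jitter_sd_s)
    e <- ev$end_s + stats::rnorm(nrow(ev), 0, an$jitter_sd_s)
    mid <- (s + e) / 2
    len <- pmax(e - s, 10)              # annotators never mark < 10 s
    s <- pmax(0, mid - len / 2)
    e <- pmin(dur_s, pmax(s + 10, mid + len / 2))
    ev <- fast_tb(start_s = s, end_s = e)
  }
  n_spur <- stats::rpois(1, an$spurious_rate_per_h * duration_h)
  if (n_spur > 0) {
    sd_ <- stats::runif(n_spur, an$spurious_dur_s[1], an$spurious_dur_s[2])
    ss <- stats::runif(n_spur, 0, pmax(1, dur_s - sd_))
    ev <- fast_tb(start_s = c(ev$start_s, ss), end_s = c(ev$end_s, ss + sd_))
  }
  if (nrow(ev) == 0) return(fast_tb(start_s = numeric(0), end_s = numeric(0)))
  normalize_events(ev)
}

# Hourly burden (min) and confirmed-scale gold hours from a true event set.
true_hour_structure <- function(events, duration_h) {
  n_hours <- max(1L, ceiling(duration_h - 1e-9))
  all_c <- structure(list(events = events, recording_duration_h = duration_h),
                     class = "consensus_annotation")
  burden <- hourly_burden(all_c)
  conf <- events[events$end_s - events$start_s >= 30, , drop = FALSE]
  conf_c <- structure(list(events = conf, recording_duration_h = duration_h),
                      class = "consensus_annotation")
  list(n_hours = n_hours, burden = burden, gold_hours = seizure_hours(conf_c))
}

mark_probability <- function(burden_min, weekend, intercept, det) {
  stats::plogis(intercept + det$slope * log(pmax(burden_min, 0.05)) +
                  det$weekend_lor * as.numeric(weekend))
}

#' Generate a complete synthetic trial cohort
#'
#' Produces, fully deterministically given `config$seed`: cohort metadata
#' (1:1 allocation, hospitals filled evenly within each group), true seizure
#' event trains for seizure neonates, two imperfect expert annotation sets,
#' an hourly clinical record drawn from the burden-dependent recognition
#' model, and a truth object (never consumed by the pipeline) holding the
#' latent events, burdens and detection probabilities.
#'
#' @param config a [cohort_config()].
#' @return list: `metadata`, `annotations` (both annotators, long form),
#'   `clinical`, `truth`.
#' @export
generate_cohort <- function(config) {
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  det <- config$detection
  an <- config$annotators
  groups <- c("algorithm", "non_algorithm")
  meta <- list(); anns <- list(); clin <- list(); truth <- list()
  origin <- as.POSIXct(paste0(config$start_window$origin, "T00:00:00"),
                       format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (g in groups) {
    n <- config$n_per_group
    hosp <- rep(sprintf("H%d", seq_len(config$n_hospitals)), length.out = n)
    for (i in seq_len(n)) {
      id <- sprintf("%s%03d", if (g == "algorithm") "A" else "N", i)
      dur_h <- min(config$duration$max_h,
                   max(config$duration$min_h,
                       stats::rlnorm(1, config$duration$meanlog,
                                     config$duration$sdlog)))
      start <- as.POSIXct(
        round(as.numeric(origin) +
                stats::runif(1, 0, config$start_window$span_days) * 86400),
        origin = "1970-01-01", tz = "UTC")
      is_sz <- stats::runif(1) < config$prevalence[[g]]
      events <- if (is_sz) gen_event_train(dur_h, config$events) else
        fast_tb(start_s = numeric(0), end_s = numeric(0))
      hs <- true_hour_structure(events, dur_h)
      strata <- hour_strata(start, hs$n_hours)
      weekend <- strata$day_type == "weekend"
      gold <- seq_len(hs$n_hours) - 1L
      is_gold <- gold %in% hs$gold_hours
      p_mark <- numeric(hs$n_hours)
      p_mark[is_gold] <- mark_probability(hs$burden[is_gold], weekend[is_gold],
                                          det$intercepts[[g]], det)
      suspected <- stats::runif(1) <
        det$p_suspected[[if (is_sz) "seizure" else "non_seizure"]]
      fm <- det$false_mark_rate[[if (suspected) "suspected" else "background"]]
      p_mark[!is_gold] <- fm
      marked <- stats::runif(hs$n_hours) < p_mark
      gold_prev <- c(FALSE, is_gold[-hs$n_hours])
      true_context <- is_gold | gold_prev
      p_asm <- ifelse(marked,
                      ifelse(true_context, det$p_asm_true_mark,
                             det$p_asm_false_mark),
                      det$asm_background_rate)
      asm <- stats::runif(hs$n_hours) < p_asm
      ann1 <- annotate_events(events, dur_h, an)
      ann2 <- annotate_events(events, dur_h, an)
      meta[[length(meta) + 1]] <- fast_tb(
        neonate_id = id, hospital = hosp[i], group = g,
        recording_duration_h = dur_h,
        start_datetime = format(start, "%Y-%m-%dT%H:%M:%S")
      )
      anns[[length(anns) + 1]] <- fast_tb(
        neonate_id = c(rep(id, nrow(ann1)), rep(id, nrow(ann2))),
        annotator_id = c(rep("E1", nrow(ann1)), rep("E2", nrow(ann2))),
        start_s = c(ann1$start_s, ann2$start_s),
        end_s = c(ann1$end_s, ann2$end_s)
      )
      clin[[length(clin) + 1]] <- fast_tb(
        neonate_id = rep(id, hs$n_hours), hour_index = gold,
        form_marked = as.integer(marked), asm_given = as.integer(asm),
        asm_therapeutic = rep(1L, hs$n_hours)
      )
      truth[[id]] <- list(
        is_seizure = is_sz, events = events, gold_hours = hs$gold_hours,
        hourly_burden = hs$burden, p_mark = p_mark
      )
    }
  }
  list(
    metadata = dplyr::bind_rows(meta),
    annotations = dplyr::bind_rows(anns),
    clinical = dplyr::bind_rows(clin),
    truth = list(neonates = truth, planted = config$planted)
  )
}

#' Configure perfect annotators (no jitter, misses, or spurious events)
#'
#' Convenience modifier: under this configuration both annotation sets equal
#' the true events, so the consensus gold standard coincides exactly with
#' the generator's confirmed-scale truth. Used to isolate the recognition
#' model from annotation noise.
#'
#' @param config a [cohort_config()].
#' @return modified config.
#' @export
perfect_annotators <- function(config) {
  config$annotators$jitter_sd_s <- 0
  config$annotators$miss_prob_short <- 0
  config$annotators$spurious_rate_per_h <- 0
  config
}

#' Calibrate the recognition model to target hour-level sensitivities
#'
#' Sets the per-group intercepts of the logistic recognition model so that
#' the expected hour-level sensitivity (identified gold hours / gold hours,
#' under the confirmed >= 30 s gold standard and faithful annotation)
#' equals the planted targets. The calibration inverts, by root finding,
#' the analytic per-hour identification probability — a gold hour H is
#' identified if H or H+1 carries a mark or an ASM dose, so
#' `P(identified) = 1 - (1 - r_H)(1 - r_{H+1})` with `r` the flagging
#' probability of each hour (recognition mark for gold hours, false-mark
#' rate for non-gold hours, background ASM everywhere) — over a large
#' simulated reference population of seizure-hour structures.
#'
#' @param config a [cohort_config()].
#' @param sens_algorithm,sens_non_algorithm target expected hour-level
#'   sensitivities, in (0, 1).
#' @param n_ref reference seizure neonates used for the inversion.
#' @return config with calibrated `detection$intercepts` and the planted
#'   targets recorded in `$planted`.
#' @export
plant_group_effect <- function(config, sens_algorithm, sens_non_algorithm,
                               n_ref = 3000) {
  stopifnot(sens_algorithm > 0, sens_algorithm < 1,
            sens_non_algorithm > 0, sens_non_algorithm < 1)
  ref <- with_seed(child_seed(config$seed, 99), {
    rows <- vector("list", n_ref)
    origin <- as.POSIXct(paste0(config$start_window$origin, "T00:00:00"),
                         format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    for (i in seq_len(n_ref)) {
      dur_h <- min(config$duration$max_h,
                   max(config$duration$min_h,
                       stats::rlnorm(1, config$duration$meanlog,
                                     config$duration$sdlog)))
      start <- as.POSIXct(
        round(as.numeric(origin) +
                stats::runif(1, 0, config$start_window$span_days) * 86400),
        origin = "1970-01-01", tz = "UTC")
      events <- gen_event_train(dur_h, config$events)
      hs <- true_hour_structure(events, dur_h)
      if (length(hs$gold_hours) == 0) next
      weekend <- hour_strata(start, hs$n_hours)$day_type == "weekend"
      idx <- hs$gold_hours + 1L
      nxt <- hs$gold_hours + 2L
      next_exists <- nxt <= hs$n_hours
      next_gold <- (hs$gold_hours + 1L) %in% hs$gold_hours
      next_burden <- ifelse(next_exists, hs$burden[pmin(nxt, hs$n_hours)], 0)
      next_weekend <- ifelse(next_exists, weekend[pmin(nxt, hs$n_hours)], FALSE)
      rows[[i]] <- fast_tb(
        burden = hs$burden[idx], weekend = weekend[idx],
        next_exists = next_exists, next_gold = next_gold,
        next_burden = next_burden, next_weekend = next_weekend
      )
    }
    dplyr::bind_rows(rows)
  })
  det <- config$detection
  bg <- det$asm_background_rate
  # expected flagging rate of a non-gold hour of a seizure neonate: mixture
  # over the suspicion state (exact for the per-hour expectation)
  p_susp <- det$p_suspected[["seizure"]]
  fm_mix <- p_susp * det$false_mark_rate[["suspected"]] +
    (1 - p_susp) * det$false_mark_rate[["background"]]
  expected_sens <- function(b0) {
    p_here <- mark_probability(ref$burden, ref$weekend, b0, det)
    r_here <- 1 - (1 - p_here) * (1 - bg)
    p_next <- mark_probability(ref$next_burden, ref$next_weekend, b0, det)
    r_next_gold <- 1 - (1 - p_next) * (1 - bg)
    r_next_nongold <- 1 - (1 - fm_mix) * (1 - bg)
    r_next <- ifelse(!ref$next_exists, 0,
                     ifelse(ref$next_gold, r_next_gold, r_next_nongold))
    mean(1 - (1 - r_here) * (1 - r_next))
  }
  solve_b0 <- function(target) {
    stats::uniroot(function(b) expected_sens(b) - target,
                   lower = -12, upper = 8, tol = 1e-8)$root
  }
  config$detection$intercepts <- c(
    algorithm = solve_b0(sens_algorithm),
    non_algorithm = solve_b0(sens_non_algorithm)
  )
  config$planted <- c(algorithm = sens_algorithm,
                      non_algorithm = sens_non_algorithm)
  config
}
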