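#' Run the full trial-evaluation pipeline
#'
#' Consensus -> clinical scoring -> accuracy statistics, reproducing the
#' trial's three result tables from raw annotation, clinical-record and
#' metadata tables:
#'
#' * `table_neonate`: per-group neonate-level confusion counts with
#'   sensitivity, specificity and false detection rate (plus between-group
#'   differences), each with a bias-corrected cluster-bootstrap CI;
#' * `table_hours`: hour-level sensitivity overall and within
#'   weekday/weekend and day/night-shift strata (when timestamps are
#'   available), with difference CIs, plus the form-level false-detection
#'   rates;
#' * `table_secondary`: burden summaries (group medians) and
#'   inappropriate-ASM proportions among seizure and non-seizure neonates.
#'
#' All estimates are kept at full precision; [format_report()] applies the
#' one-decimal half-up presentation rounding.
#'
#' @param annotations,clinical,metadata input tables (see [trial-io]).
#' @param boot a [bootstrap_config()]; use a few thousand iterations for
#'   exploration, 100000 for confirmatory runs.
#' @param min_overlap_s consensus confirmation threshold in seconds.
#' @param strata compute weekday/weekend and shift strata (requires
#'   `start_datetime` in metadata).
#' @return list of class `trial_report` with the three tables, the
#'   interaction tests (`interaction_day_type`, `interaction_shift`), the
#'   scored intermediates (`scored`), and run metadata.
#' @export
run_pipeline <- function(annotations, clinical, metadata,
                         boot = bootstrap_config(n_iter = 2000),
                         min_overlap_s = 30, strata = TRUE) {
  v <- validate_inputs(annotations, clinical, metadata)
  if (length(v$errors) > 0) {
    stop(paste(c("invalid inputs:", v$errors), collapse = "\n  "),
         call. = FALSE)
  }
  consensus <- build_consensus(annotations, metadata,
                               min_overlap_s = min_overlap_s)
  scored <- score_cohort(clinical, consensus, metadata)
  nn <- scored$neonates
  groups <- c("algorithm", "non_algorithm")

  cl <- function(d) paste(d$group, d$hospital, sep = ":")
  seeded <- function(k) {
    cfg <- boot
    cfg$seed <- child_seed(boot$seed, k)
    cfg
  }
  metric_rows <- list()
  k <- 0
  add_metric <- function(label, stat_fn, num_fn, den_fn) {
    k <<- k + 1
    rows <- lapply(groups, function(g) {
      d <- nn[nn$group == g, ]
      ci <- bc_bootstrap_ci(d, stat_fn, cl(d), config = seeded(k))
      dplyr::bind_cols(tibble::tibble(metric = label, group = g,
                                      n_num = num_fn(d), n_den = den_fn(d)), ci)
    })
    k <<- k + 1
    dci <- difference_ci(nn, stat_fn, nn$group, "algorithm", "non_algorithm",
                         config = seeded(k))
    rows[[3]] <- dplyr::bind_cols(
      tibble::tibble(metric = label, group = "difference",
                     n_num = NA_integer_, n_den = NA_integer_), dci)
    dplyr::bind_rows(rows)
  }

  sens_fn <- function(d) {
    cc <- neonate_confusion(d, allow_duplicates = TRUE)
    sensitivity(cc$tp, cc$fn)
  }
  spec_fn <- function(d) {
    cc <- neonate_confusion(d, allow_duplicates = TRUE)
    specificity(cc$tn, cc$fp)
  }
  fdr_fn <- function(d) {
    cc <- neonate_confusion(d, allow_duplicates = TRUE)
    false_detection_rate(cc$fp, cc$tp)
  }
  table_neonate <- dplyr::bind_rows(
    add_metric("sensitivity", sens_fn,
               function(d) sum(d$gold_positive & d$clinical_positive),
               function(d) sum(d$gold_positive)),
    add_metric("specificity", spec_fn,
               function(d) sum(!d$gold_positive & !d$clinical_positive),
               function(d) sum(!d$gold_positive)),
    add_metric("false_detection_rate", fdr_fn,
               function(d) sum(!d$gold_positive & d$clinical_positive),
               function(d) sum(d$clinical_positive))
  )
  confusion <- dplyr::bind_rows(lapply(groups, function(g) {
    cc <- neonate_confusion(nn[nn$group == g, ])
    tibble::tibble(group = g, n = sum(nn$group == g),
                   n_seizure = sum(nn$gold_positive[nn$group == g]),
                   tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn)
  }))

  hsens_fn <- function(d) hour_sensitivity(sum(d$n_identified), sum(d$n_gold_hours))
  ffdr_fn <- function(d) form_false_detection_rate(sum(d$n_false_detections),
                                                   sum(d$n_marked_hours))
  hs <- scored$hour_scores
  has_strata <- strata && "day_type" %in% names(hs) && !anyNA(hs$day_type)
  strat_defs <- list(overall = rep(TRUE, nrow(hs)))
  if (has_strata) {
    strat_defs <- c(strat_defs, list(
      weekday = hs$day_type == "weekday", weekend = hs$day_type == "weekend",
      day_shift = hs$shift == "day", night_shift = hs$shift == "night"
    ))
  }
  table_hours <- dplyr::bind_rows(lapply(names(strat_defs), function(sname) {
    sub <- hs[strat_defs[[sname]], ]
    per_neonate <- dplyr::summarise(
      dplyr::group_by(sub, .data$neonate_id, .data$group, .data$hospital),
      n_gold_hours = sum(.data$gold_seizure_hour),
      n_identified = sum(.data$identified[.data$gold_seizure_hour]),
      n_marked_hours = sum(.data$form_marked),
      n_false_detections = sum(.data$false_detection),
      .groups = "drop"
    )
    rows <- lapply(groups, function(g) {
      d <- per_neonate[per_neonate$group == g, ]
      k <<- k + 1
      ci <- bc_bootstrap_ci(d, hsens_fn, cl(d), config = seeded(k))
      dplyr::bind_cols(tibble::tibble(
        stratum = sname, metric = "hour_sensitivity", group = g,
        n_seizure_neonates = sum(d$n_gold_hours > 0),
        n_num = sum(d$n_identified), n_den = sum(d$n_gold_hours)), ci)
    })
    k <<- k + 1
    dci <- difference_ci(per_neonate, hsens_fn, per_neonate$group,
                         "algorithm", "non_algorithm", config = seeded(k))
    rows[[3]] <- dplyr::bind_cols(tibble::tibble(
      stratum = sname, metric = "hour_sensitivity", group = "difference",
      n_seizure_neonates = NA_integer_,
      n_num = NA_integer_, n_den = NA_integer_), dci)
    if (sname == "overall") {
      rows <- c(rows, lapply(groups, function(g) {
        d <- per_neonate[per_neonate$group == g, ]
        k <<- k + 1
        ci <- bc_bootstrap_ci(d, ffdr_fn, cl(d), config = seeded(k))
        dplyr::bind_cols(tibble::tibble(
          stratum = sname, metric = "form_false_detection_rate", group = g,
          n_seizure_neonates = NA_integer_,
          n_num = sum(d$n_false_detections),
          n_den = sum(d$n_marked_hours)), ci)
      }))
      k <<- k + 1
      dci2 <- difference_ci(per_neonate, ffdr_fn, per_neonate$group,
                            "algorithm", "non_algorithm", config = seeded(k))
      rows[[6]] <- dplyr::bind_cols(tibble::tibble(
        stratum = sname, metric = "form_false_detection_rate",
        group = "difference", n_seizure_neonates = NA_integer_,
        n_num = NA_integer_, n_den = NA_integer_), dci2)
    }
    dplyr::bind_rows(rows)
  }))

  interactions <- list()
  if (has_strata) {
    gold_rows <- hs[hs$gold_seizure_hour, ]
    interactions$interaction_day_type <- interaction_test(tibble::tibble(
      group = gold_rows$group, period = gold_rows$day_type,
      identified = gold_rows$identified))
    interactions$interaction_shift <- interaction_test(tibble::tibble(
      group = gold_rows$group, period = gold_rows$shift,
      identified = gold_rows$identified))
  }

  asm_fn <- function(d) pct(sum(d$any_inappropriate_asm), nrow(d))
  table_secondary <- dplyr::bind_rows(lapply(
    list(c("seizure", TRUE), c("non_seizure", FALSE)),
    function(sub) {
      keep <- nn$gold_positive == as.logical(sub[2])
      rows <- lapply(groups, function(g) {
        d <- nn[keep & nn$group == g, ]
        k <<- k + 1
        ci <- bc_bootstrap_ci(d, asm_fn, cl(d), config = seeded(k))
        dplyr::bind_cols(tibble::tibble(
          metric = "any_inappropriate_asm", subgroup = sub[1], group = g,
          n_num = sum(d$any_inappropriate_asm), n_den = nrow(d)), ci)
      })
      k <<- k + 1
      dci <- difference_ci(nn[keep, ], asm_fn, nn$group[keep],
                           "algorithm", "non_algorithm", config = seeded(k))
      rows[[3]] <- dplyr::bind_cols(tibble::tibble(
        metric = "any_inappropriate_asm", subgroup = sub[1],
        group = "difference", n_num = NA_integer_, n_den = NA_integer_), dci)
      dplyr::bind_rows(rows)
    }))

  burden <- burden_table(consensus)
  burden <- dplyr::left_join(burden,
                             metadata[, c("neonate_id", "group")],
                             by = "neonate_id")
  burden_medians <- dplyr::summarise(
    dplyr::group_by(burden[burden$n_events > 0, ], .data$group),
    total_burden_min = stats::median(.data$total_burden_min),
    max_hourly_burden_min_per_h = stats::median(.data$max_hourly_burden_min_per_h),
    median_duration_s = stats::median(.data$median_duration_s),
    n = dplyr::n(), .groups = "drop"
  )

  structure(c(list(
    confusion = confusion,
    table_neonate = table_neonate,
    table_hours = table_hours,
    table_secondary = table_secondary,
    burden_medians = burden_medians,
    scored = scored,
    burden = burden,
    metadata = list(
      n_boot = boot$n_iter, alpha = boot$alpha, seed = boot$seed,
      min_overlap_s = min_overlap_s,
      validation_warnings = v$warnings,
      version = as.character(utils::packageVersion("cotside"))
    )
  ), interactions), class = "trial_report")
}

#' Presentation-ready report tables
#'
#' Applies the one-decimal half-up rounding to every estimate and CI bound
#' of a [run_pipeline()] report.
#'
#' @param report a `trial_report`.
#' @return list of tibbles with rounded `estimate`, `ci_low`, `ci_high`.
#' @export
format_report <- function(report) {
  rnd <- function(tab) {
    for (col in intersect(c("estimate", "ci_low", "ci_high"), names(tab))) {
      tab[[col]] <- round_half_up(tab[[col]], 1)
    }
    tab
  }
  list(
    confusion = report$confusion,
    table_neonate = rnd(report$table_neonate),
    table_hours = rnd(report$table_hours),
    table_secondary = rnd(report$table_secondary),
    burden_medians = report$burden_medians
  )
}

#' Write a report's tables to CSV
#'
#' @param report a `trial_report`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fr <- format_report(report)
  paths <- character(0)
  for (nm in names(fr)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(fr[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
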