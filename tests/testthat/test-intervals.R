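test_that("normalize_events sorts, merges and preserves coverage", {
  expect_equal(as.data.frame(normalize_events(data.frame(start_s = 0, end_s = 60))),
               data.frame(start_s = 0, end_s = 60))
  expect_equal(
    as.data.frame(normalize_events(data.frame(start_s = c(0, 40), end_s = c(50, 90)))),
    data.frame(start_s = 0, end_s = 90)
  )
  out <- normalize_events(data.frame(start_s = c(100, 0, 20),
                                     end_s = c(130, 20, 35)))
  expect_equal(as.data.frame(out),
               data.frame(start_s = c(0, 100), end_s = c(35, 130)))
  expect_equal(sec_cover(out),
               sec_cover(data.frame(start_s = c(100, 0, 20),
                                    end_s = c(130, 20, 35))))

  expect_error(normalize_events(data.frame(start_s = c(0, 50), end_s = c(10, 50))),
               "row 2")
})

test_that("normalized output equals per-second union oracle on random sets", {
  set.seed(421)
  for (i in 1:60) {
    ev <- rand_events(sample(1:12, 1))
    out <- normalize_events(ev)
    oracle <- secs_to_intervals(sec_cover(ev))
    expect_equal(as.data.frame(out), oracle)
    # disjoint and sorted
    if (nrow(out) > 1) {
      expect_true(all(diff(out$start_s) > 0))
      expect_true(all(out$start_s[-1] > out$end_s[-nrow(out)]))
    }
  }
})

test_that("intersect_events matches the per-second membership oracle", {
  a <- normalize_events(data.frame(start_s = 0, end_s = 60))
  expect_equal(nrow(intersect_events(a, data.frame(start_s = numeric(0),
                                                   end_s = numeric(0)))), 0)
  expect_equal(as.data.frame(intersect_events(a, a)),
               data.frame(start_s = 0, end_s = 60))
  out <- intersect_events(
    normalize_events(data.frame(start_s = 0, end_s = 100)),
    normalize_events(data.frame(start_s = c(40, 90), end_s = c(70, 150)))
  )
  expect_equal(as.data.frame(out),
               data.frame(start_s = c(40, 90), end_s = c(70, 100)))

  set.seed(422)
  for (i in 1:60) {
    a <- normalize_events(rand_events(sample(1:10, 1)))
    b <- normalize_events(rand_events(sample(1:10, 1)))
    out <- intersect_events(a, b)
    oracle <- secs_to_intervals(intersect(sec_cover(a), sec_cover(b)))
    expect_equal(as.data.frame(out), oracle)
    # symmetry and containment in each input
    expect_equal(as.data.frame(intersect_events(b, a)), as.data.frame(out))
    expect_true(all(sec_cover(out) %in% sec_cover(a)))
    expect_true(all(sec_cover(out) %in% sec_cover(b)))
  }
})

test_that("confirm_events keeps segments at or above the 30 s threshold", {
  expect_equal(nrow(confirm_events(data.frame(start_s = 0, end_s = 29.9))), 0)
  expect_equal(as.data.frame(confirm_events(data.frame(start_s = 0, end_s = 30))),
               data.frame(start_s = 0, end_s = 30))
  out <- confirm_events(data.frame(start_s = c(0, 50, 200),
                                   end_s = c(20, 95, 600)))
  expect_equal(as.data.frame(out),
               data.frame(start_s = c(50, 200), end_s = c(95, 600)))
  expect_error(confirm_events(data.frame(start_s = 0, end_s = 50), -1),
               "non-negative")
})

test_that("identical annotators recover exactly the >= 30 s events", {
  set.seed(423)
  for (i in 1:20) {
    ev <- normalize_events(rand_events(sample(1:8, 1), min_len = 10,
                                       max_len = 200))
    cons <- consensus_annotation(ev, ev, recording_duration_h = 4)
    kept <- ev[ev$end_s - ev$start_s >= 30, ]
    expect_equal(as.data.frame(cons$events), as.data.frame(kept),
                 ignore_attr = TRUE)
  }
  # events of 10-30 s are dropped even under perfect agreement
  short <- data.frame(start_s = c(0, 100), end_s = c(15, 129))
  cons <- consensus_annotation(short, short, recording_duration_h = 1)
  expect_false(is_seizure_neonate(cons))
})

test_that("seizure hours use recording-anchored bins and clip overruns", {
  mk <- function(ev, dur = 3) consensus_annotation(ev, ev, dur)
  expect_equal(seizure_hours(mk(data.frame(start_s = 100, end_s = 200))), 0L)
  expect_equal(seizure_hours(mk(data.frame(start_s = 3500, end_s = 3700))),
               c(0L, 1L))
  expect_equal(
    seizure_hours(mk(data.frame(start_s = c(0, 7300, 7500),
                                end_s = c(40, 7400, 7600)))),
    c(0L, 2L)
  )
  # an event beyond the recording is clipped with a warning
  c_over <- consensus_annotation(data.frame(start_s = 3500, end_s = 4000),
                                 data.frame(start_s = 3500, end_s = 4000),
                                 recording_duration_h = 1)
  expect_warning(h <- seizure_hours(c_over), "clipped")
  expect_equal(h, 0L)
  expect_equal(seizure_hours(mk(data.frame(start_s = c(0, 7300, 7500),
                                           end_s = c(40, 7400, 7600)))),
               sort(unique(sec_cover(data.frame(start_s = c(0, 7300, 7500),
                                                end_s = c(40, 7400, 7600))) %/% 3600)))
})

test_that("burden summaries match the per-second accumulation oracle", {
  mk <- function(ev, dur = 3) consensus_annotation(ev, ev, dur)
  one <- burden_summary(mk(data.frame(start_s = 0, end_s = 60)))
  expect_equal(one$total_burden_min, 1)
  expect_equal(one$max_hourly_burden_min_per_h, 1)
  expect_equal(one$median_duration_s, 60)

  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  none <- burden_summary(consensus_annotation(empty, empty, 2))
  expect_equal(none$total_burden_min, 0)
  expect_equal(none$max_hourly_burden_min_per_h, 0)
  expect_true(is.na(none$median_duration_s))

  ev <- data.frame(start_s = c(0, 3500, 4000), end_s = c(120, 3700, 4090))
  bs <- burden_summary(mk(ev))
  secs <- sec_cover(ev)
  expect_equal(bs$total_burden_min, length(secs) / 60)        # 410 s
  expect_equal(bs$max_hourly_burden_min_per_h,
               max(table(secs %/% 3600)) / 60)                # 190 s in hour 1
  expect_equal(bs$median_duration_s, 120)
})

test_that("hourly burden conserves total burden and flags seizure neonates", {
  set.seed(424)
  for (i in 1:25) {
    ev <- normalize_events(rand_events(sample(1:10, 1), min_len = 30,
                                       max_len = 1200))
    cons <- consensus_annotation(ev, ev, recording_duration_h = 4)
    hb <- hourly_burden(cons)
    expect_equal(sum(hb), burden_summary(cons)$total_burden_min)
    expect_true(all(hb <= 60 + 1e-9))
    expect_equal(length(seizure_hours(cons)) > 0, is_seizure_neonate(cons))
  }
})

test_that("build_consensus pairs annotators and validates ids", {
  ann <- data.frame(
    neonate_id = c("a", "a", "b"),
    annotator_id = c("E1", "E2", "E1"),
    start_s = c(0, 10, 50), end_s = c(100, 90, 200)
  )
  meta <- data.frame(neonate_id = c("a", "b"), recording_duration_h = c(2, 2))
  cons <- build_consensus(ann, meta)
  expect_equal(as.data.frame(cons[["a"]]$events),
               data.frame(start_s = 10, end_s = 90))
  expect_equal(nrow(cons[["b"]]$events), 0)  # only one annotator marked b

  tab <- consensus_table(cons)
  expect_equal(tab$neonate_id, "a")
  expect_equal(tab$duration_s, 80)

  expect_error(build_consensus(ann[1, ], meta), "two annotators")
  expect_error(
    build_consensus(transform(ann, neonate_id = c("a", "a", "zzz")), meta),
    "absent from metadata"
  )
})
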