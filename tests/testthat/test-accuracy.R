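test_that("metrics handle boundaries and undefined denominators", {
  expect_equal(sensitivity(10, 0), 100)
  expect_equal(hour_sensitivity(0, 10), 0)
  expect_true(is.na(sensitivity(0, 0)))
  expect_true(is.na(form_false_detection_rate(0, 0)))
  expect_false(is.nan(sensitivity(0, 0)))
})

test_that("presentation rounding is half away from zero", {
  expect_equal(round_half_up(81.25), 81.3)
  expect_equal(round_half_up(63.45), 63.5)
  expect_equal(round_half_up(-4.755, 1), -4.8)
  expect_equal(round_half_up(-8.22, 1), -8.2)
  expect_equal(round_half_up(c(0.04, 0.05, 0.06)), c(0, 0.1, 0.1))
})

test_that("sample-size arithmetic reproduces the recruitment inflation", {
  expect_equal(required_group_size(33, 0.40), 83L)
  expect_equal(required_group_size(33, 0.25), 132L)
  expect_equal(required_group_size(10, 1.0), 10L)
  expect_error(required_group_size(10, 0), "prevalence")
  expect_error(required_group_size(10, -0.2), "prevalence")
})

test_that("two-sample normal approximation for seizure-neonate count", {
  # delta 25 pp, SD 35 pp, power 80%, alpha 5%: formula gives 31 per group
  expect_equal(required_seizure_neonates(25, 35, 0.8, 0.05), 31L)
  # unceiled value quadruples when the SD doubles
  raw <- function(delta, sd) {
    2 * (qnorm(0.975) + qnorm(0.8))^2 * sd^2 / delta^2
  }
  expect_equal(raw(25, 70) / raw(25, 35), 4)
  expect_equal(required_seizure_neonates(25, 70, 0.8, 0.05), 124L)
  # an enormous effect needs only one neonate
  expect_equal(required_seizure_neonates(1e6, 35), 1L)
})

test_that("a constant statistic gives a degenerate interval", {
  d <- data.frame(x = rnorm(10))
  ci <- bc_bootstrap_ci(d, function(df) 42, rep("c1", 10),
                        bootstrap_config(n_iter = 50, seed = 2))
  expect_equal(ci$estimate, 42)
  expect_equal(ci$ci_low, 42)
  expect_equal(ci$ci_high, 42)
})

test_that("exhaustive three-neonate enumeration matches the BC oracle", {
  # all 27 equally likely resamples of one cluster of three neonates;
  # oracle values computed independently from the exact resample
  # distribution (strictly-less + half-ties bias correction, type-1
  # quantiles of the 27 sorted means)
  d <- data.frame(x = c(1, 2, 10))
  grid <- expand.grid(i = 1:3, j = 1:3, k = 1:3)
  idx <- lapply(seq_len(27), function(r) as.integer(grid[r, ]))
  ci <- bc_bootstrap_ci(d, function(df) mean(df$x), rep("c1", 3),
                        bootstrap_config(n_iter = 27, seed = 5, alpha = 0.2),
                        resample_indices = idx)
  expect_equal(ci$estimate, 13 / 3)
  expect_equal(ci$ci_low, 4 / 3)
  expect_equal(ci$ci_high, 22 / 3)
})

test_that("near-symmetric statistics give BC close to percentile intervals", {
  set.seed(61)
  d <- data.frame(y = rep(c(0, 1), each = 50))
  cfg <- bootstrap_config(n_iter = 10000, seed = 31)
  bc <- bc_bootstrap_ci(d, function(df) mean(df$y), rep("c1", 100), cfg)
  # independent percentile oracle: own resampling, own quantile code
  set.seed(777)
  boots <- replicate(10000, mean(d$y[sample.int(100, 100, replace = TRUE)]))
  perc <- unname(quantile(boots, c(0.025, 0.975), type = 1))
  expect_lt(abs(bc$ci_low - perc[1]), 0.02)
  expect_lt(abs(bc$ci_high - perc[2]), 0.02)
})

test_that("forcing z0 to zero reduces BC to the percentile interval", {
  set.seed(62)
  d <- data.frame(y = rbinom(40, 1, 0.3))
  cl <- rep(c("a", "b"), each = 20)
  idx_by <- split(1:40, cl)
  set.seed(63)
  idx <- replicate(500, unlist(lapply(idx_by, function(ix)
    sample(ix, length(ix), replace = TRUE))), simplify = FALSE)
  ci <- bc_bootstrap_ci(d, function(df) mean(df$y), cl,
                        bootstrap_config(n_iter = 500, seed = 9),
                        resample_indices = idx, force_z0_zero = TRUE)
  stats <- sort(vapply(idx, function(ix) mean(d$y[ix]), numeric(1)))
  expect_equal(ci$ci_low, stats[max(1, ceiling(0.025 * 500))])
  expect_equal(ci$ci_high, stats[ceiling(0.975 * 500)])
})

test_that("every resample preserves cluster sizes exactly", {
  d <- data.frame(y = rnorm(30))
  cl <- rep(c("g1:h1", "g1:h2", "g2:h1"), each = 10)
  expect_no_error(
    bc_bootstrap_ci(d, function(df) mean(df$y), cl,
                    bootstrap_config(n_iter = 100, seed = 4),
                    check_cluster_sizes = TRUE)
  )
})

test_that("interval width shrinks as cluster sizes grow", {
  widths <- vapply(c(25, 100, 400), function(n) {
    set.seed(70)
    d <- data.frame(y = rbinom(n, 1, 0.5))
    ci <- bc_bootstrap_ci(d, function(df) mean(df$y), rep("c", n),
                          bootstrap_config(n_iter = 2000, seed = 71))
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the same seed gives bit-identical intervals", {
  d <- data.frame(y = rbinom(60, 1, 0.4))
  cl <- rep(c("a", "b", "c"), each = 20)
  cfg <- bootstrap_config(n_iter = 400, seed = 123)
  ci1 <- bc_bootstrap_ci(d, function(df) mean(df$y), cl, cfg)
  ci2 <- bc_bootstrap_ci(d, function(df) mean(df$y), cl, cfg)
  expect_identical(ci1, ci2)
})

test_that("difference of identical groups straddles zero", {
  set.seed(72)
  d <- data.frame(y = rep(rbinom(30, 1, 0.5), 2),
                  hospital = rep(c("h1", "h2"), 30))
  grp <- rep(c("A", "B"), each = 30)
  ci <- difference_ci(d, function(df) 100 * mean(df$y), grp, "A", "B",
                      config = bootstrap_config(n_iter = 500, seed = 73))
  expect_equal(ci$estimate, 0)
  expect_lte(ci$ci_low, 0)
  expect_gte(ci$ci_high, 0)
})

test_that("undefined resample statistics are dropped and counted", {
  # a cluster of one zero-denominator neonate makes some resamples undefined
  d <- data.frame(num = c(1, 2, 0, 1), den = c(2, 2, 0, 2))
  cl <- c("a", "a", "a", "a")
  st <- function(df) {
    den <- sum(df$den)
    if (den == 0) return(NA_real_)
    sum(df$num) / den
  }
  expect_message(
    ci <- bc_bootstrap_ci(d, st, cl, bootstrap_config(n_iter = 2000, seed = 77)),
    "undefined"
  )
  expect_gte(ci$n_dropped, 1)
  expect_equal(ci$n_boot + ci$n_dropped, 2000)
})

test_that("saturated interaction models recover log odds-ratio contrasts", {
  # aggregated 2x2x2 cell table with chosen identification probabilities
  mk_tab <- function(p) {
    cells <- expand.grid(group = c("alg", "non"), period = c("wd", "we"))
    do.call(rbind, lapply(seq_len(4), function(i) {
      n1 <- c(30, 40, 25, 35)[i]
      n0 <- c(50, 45, 55, 60)[i]
      data.frame(group = cells$group[i], period = cells$period[i],
                 identified = c(1, 0), weight = c(n1, n0) * p)
    }))
  }
  tab <- mk_tab(1)
  res <- interaction_test(tab)
  expect_true(res$converged)
  # closed form: beta3 = log(OR_we / OR_wd) from the cell counts
  or_wd <- (35 / 60) / (25 / 55)   # non vs alg at weekday? keep orientation
  lo <- function(n1, n0) log(n1 / n0)
  b3 <- (lo(35, 60) - lo(25, 55)) - (lo(40, 45) - lo(30, 50))
  expect_lt(abs(unname(res$coefficients[4]) - b3), 1e-6)
  expect_true(res$interaction_p >= 0 && res$interaction_p <= 1)

  # equal odds ratios in both periods: interaction vanishes
  eq <- rbind(
    data.frame(group = "alg", period = "wd", identified = c(1, 0), weight = c(30, 30)),
    data.frame(group = "non", period = "wd", identified = c(1, 0), weight = c(20, 40)),
    data.frame(group = "alg", period = "we", identified = c(1, 0), weight = c(45, 45)),
    data.frame(group = "non", period = "we", identified = c(1, 0), weight = c(22, 44))
  )
  res_eq <- interaction_test(eq)
  expect_lt(abs(unname(res_eq$coefficients[4])), 1e-6)

  expect_error(interaction_test(data.frame(group = "alg", period = "wd",
                                           identified = 1)),
               "cell")
})
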