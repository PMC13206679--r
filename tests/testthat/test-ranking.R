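# hand-built table used across several blocks
tiny_table <- function() {
  expand <- expand.grid(technique = c("baseline", "aug_a", "aug_b"),
                        dataset = c("d1", "d2"),
                        architecture = c("cnn", "vit"),
                        metric = c("m1", "m2"),
                        stringsAsFactors = FALSE)
  # deterministic values: baseline 80, aug_a 80 + bonus, aug_b 80 - 1
  bonus <- ifelse(expand$dataset == "d1", 2, 4)
  expand$value <- ifelse(expand$technique == "aug_a", 80 + bonus,
                         ifelse(expand$technique == "aug_b", 79, 80))
  expand
}

test_that("cumulative scores sum metric values over the requested subset", {
  t <- data.frame(technique = "x", dataset = "d", architecture = "a",
                  metric = paste0("m", 1:5),
                  value = c(90, 80, 85, 70, 95))
  expect_equal(cumulative_score(t, "x"), 420)
  expect_equal(cumulative_score(t, "x", datasets = "other"), 0)
  t2 <- rbind(t, transform(t, architecture = "b"))
  expect_equal(cumulative_score(t2, "x"), 840)
  expect_error(cumulative_score(t, "nope"), class = "missing_technique_error")
})

test_that("relative improvement is the score difference and is antisymmetric", {
  t <- tiny_table()
  # aug_a: +2 per d1 cell (4 cells), +4 per d2 cell (4 cells) = 8 + 16
  expect_equal(relative_improvement(t, "aug_a", "baseline"), 24)
  expect_equal(relative_improvement(t, "baseline", "baseline"), 0)
  expect_equal(relative_improvement(t, "baseline", "aug_a"), -24)
  # additivity over disjoint dataset subsets
  expect_equal(relative_improvement(t, "aug_a", "baseline", datasets = "d1") +
                 relative_improvement(t, "aug_a", "baseline", datasets = "d2"),
               relative_improvement(t, "aug_a", "baseline"))
})

test_that("mean improvement CI uses the SEM across datasets with z = 1.96", {
  t <- tiny_table()
  ci <- mean_improvement_ci(t, "aug_a", "baseline")
  # per-dataset improvements: d1 = 8, d2 = 16
  expect_equal(ci$per_group, c(8, 16))
  expect_equal(ci$mean, 12)
  expect_equal(ci$half_width,
               stats::qnorm(0.975) * stats::sd(c(8, 16)) / sqrt(2))
  # hand case: improvements 1, 2, 3 -> half-width 1.96 * 1/sqrt(3)
  t3 <- data.frame(technique = rep(c("b", "x"), each = 3),
                   dataset = rep(c("d1", "d2", "d3"), 2),
                   architecture = "a", metric = "m",
                   value = c(10, 10, 10, 11, 12, 13))
  ci3 <- mean_improvement_ci(t3, "x", "b")
  expect_equal(ci3$mean, 2)
  expect_equal(ci3$half_width, stats::qnorm(0.975) / sqrt(3),
               tolerance = 1e-12)
  # all equal improvements: zero width
  tz <- transform(t3, value = c(10, 10, 10, 12, 12, 12))
  expect_equal(mean_improvement_ci(tz, "x", "b")$half_width, 0)
  # single dataset: SEM undefined
  t1 <- t3[t3$dataset == "d1", ]
  expect_error(mean_improvement_ci(t1, "x", "b"),
               class = "insufficient_groups_error")
})

test_that("percentage improvement averages per-dataset percent changes", {
  t <- data.frame(technique = rep(c("b", "x"), each = 2),
                  dataset = rep(c("d1", "d2"), 2),
                  architecture = "a", metric = "m",
                  value = c(400, 400, 404, 440))
  expect_equal(percent_improvement(t, "x", "b", "a"), mean(c(1, 10)))
  # symmetric +10% / -10% cancels
  ts <- transform(t, value = c(400, 400, 440, 360))
  expect_equal(percent_improvement(ts, "x", "b", "a"), 0)
  expect_equal(percent_improvement(t, "b", "b", "a"), 0)
  tz <- transform(t, value = c(0, 400, 4, 440))
  expect_error(percent_improvement(tz, "x", "b", "a"),
               class = "undefined_percentage_error")
})

test_that("composite score is the plain mean of a variant's metrics", {
  t <- data.frame(technique = "x", dataset = "d", architecture = "a",
                  metric = c("m1", "m2", "m3"), value = c(80, 90, 100))
  expect_equal(composite_score(t, "x", "a"), 90)
  expect_error(composite_score(t, "x", "missing"),
               class = "missing_data_error")
})

test_that("coefficient of variation is sd over |mean| and scale-free", {
  expect_equal(coefficient_of_variation(c(10, 20, 30)), 0.5)
  expect_equal(coefficient_of_variation(c(7, 7, 7)), 0)
  v <- c(3, 9, 14, 2)
  expect_equal(coefficient_of_variation(v * 17),
               coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)),
               class = "undefined_cv_error")
  expect_error(coefficient_of_variation(5), class = "undefined_cv_error")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  res <- paired_ttest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value,
               2 * stats::pt(res$t_statistic, df = 2, lower.tail = FALSE))
  flipped <- paired_ttest(c(0, 0, 0), c(1, 2, 3))
  expect_equal(flipped$t_statistic, -res$t_statistic)
  expect_equal(flipped$p_value, res$p_value)
  same <- paired_ttest(c(4, 5, 6), c(4, 5, 6))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
})

test_that("paired t-test agrees with a sign-flip permutation oracle", {
  set.seed(77)
  for (i in 1:6) {
    n <- sample(5:9, 1)
    a <- stats::rnorm(n, mean = 0.4)
    b <- stats::rnorm(n)
    res <- paired_ttest(a, b)
    d <- a - b
    # exact enumeration of all 2^n sign assignments of the differences
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(n))
    perm_t <- apply(signs * rep(d, each = nrow(signs)), 1, tstat)
    p_perm <- mean(abs(perm_t) >= abs(res$t_statistic) - 1e-12)
    # the permutation p moves in steps of 2/2^n (two-sided atoms), so the
    # agreement bound is that granularity plus approximation slack
    expect_lt(abs(res$p_value - p_perm), 2 / 2^n + 0.05)
  }
})

test_that("overhead sums per-epoch differences and validates coverage", {
  t <- make_timing_fixture(n_experiments = 1, n_epochs = 100,
                           overheads = c(aug = 0.45), jitter_sd = 0,
                           seed = 1)
  expect_equal(overhead(t, "aug", "baseline"), 45)
  expect_equal(overhead(t, "baseline", "baseline"), 0)
  # additivity over experiments
  t2 <- make_timing_fixture(n_experiments = 3, n_epochs = 50,
                            overheads = c(aug = 0.2), jitter_sd = 0,
                            seed = 2)
  expect_equal(overhead(t2, "aug", "baseline"), 3 * 50 * 0.2)
  broken <- t[!(t$technique == "aug" & t$epoch == 100), ]
  expect_error(overhead(broken, "aug", "baseline"),
               class = "coverage_mismatch_error")
})

test_that("timing analysis flags planted overheads against the baseline", {
  t <- make_timing_fixture(n_experiments = 6, n_epochs = 20,
                           overheads = c(slow = 0.5, light = 0.001),
                           jitter_sd = 0.02, seed = 11)
  res <- timing_analysis(t, "baseline")
  slow <- res[res$technique == "slow", ]
  expect_gt(slow$overhead_seconds, 0)
  expect_true(slow$significant)
})

test_that("ranking orders by cumulative score with competition ties", {
  t <- tiny_table()
  rep_ <- build_ranking(t, "baseline")
  expect_identical(rep_$technique, c("aug_a", "baseline", "aug_b"))
  expect_identical(rep_$rank, c(1L, 2L, 3L))
  expect_equal(rep_$relative_improvement[rep_$technique == "baseline"], 0)
  # regenerating the report is deterministic
  expect_identical(build_ranking(t, "baseline"), rep_)
  # tie: duplicate the baseline under a new name
  t_tie <- rbind(t, transform(t[t$technique == "baseline", ],
                              technique = "copycat"))
  rep_tie <- build_ranking(t_tie, "baseline")
  expect_identical(sort(rep_tie$rank), c(1L, 2L, 2L, 4L))
})

test_that("a strictly dominant technique is always ranked first", {
  set.seed(31)
  for (i in 1:5) {
    t <- make_metrics_fixture(n_techniques = 5, n_datasets = 3,
                              n_architectures = 2, planted_best = "winner",
                              seed = i)
    rep_ <- build_ranking(t, "baseline")
    expect_identical(rep_$technique[1], "winner")
    expect_gt(relative_improvement(t, "winner", "baseline"), 0)
  }
})

test_that("metrics and report tables round-trip through CSV", {
  t <- make_metrics_fixture(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(t, path, row.names = FALSE)
  t2 <- read_metrics_table(path)
  expect_equal(t2$value, t$value)
  rep_ <- build_ranking(t2, "baseline")
  out_csv <- withr::local_tempfile(fileext = ".csv")
  write_ranking_report(rep_, csv_path = out_csv)
  back <- utils::read.csv(out_csv)
  expect_equal(back$cumulative_score, rep_$cumulative_score)
  bad <- data.frame(technique = "x", wrong = 1)
  bad_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_metrics_table(bad_path), class = "invalid_table_error")
})
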