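# Benchmark scoring arithmetic: cumulative scores, improvements, confidence
# intervals, coefficients of variation, paired t-tests, timing overhead, and
# the unified technique ranking. Metric values are consumed on a 0-100 scale
# so cumulative scores land on the customary magnitudes (hundreds to
# thousands per benchmark).

#' Validate a long-format metrics table
#'
#' A metrics table has one row per (technique, dataset, architecture, metric)
#' cell with a finite numeric `value`; the key must be unique.
#'
#' @param t A data.frame with columns `technique`, `dataset`, `architecture`,
#'   `metric`, `value`.
#' @return The table, invisibly, after validation.
#' @export
validate_metrics_table <- function(t) {
  need <- c("technique", "dataset", "architecture", "metric", "value")
  if (!is.data.frame(t) || !all(need %in% names(t))) {
    sulba_stop(paste("metrics table needs columns:",
                     paste(need, collapse = ", ")),
               "invalid_table_error")
  }
  if (!all(is.finite(t$value))) {
    sulba_stop("metric values must be finite", "invalid_table_error")
  }
  key <- paste(t$technique, t$dataset, t$architecture, t$metric, sep = "\r")
  if (anyDuplicated(key)) {
    sulba_stop("duplicate (technique, dataset, architecture, metric) keys",
               "invalid_table_error")
  }
  invisible(t)
}

#' Read a metrics table from CSV
#'
#' Expects the header `technique,dataset,architecture,metric,value`.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_metrics_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metrics_table(t)
  t
}

#' Read a per-epoch timing table from CSV
#'
#' Expects the header `technique,experiment,epoch,seconds`.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_timing_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("technique", "experiment", "epoch", "seconds")
  if (!all(need %in% names(t))) {
    sulba_stop(paste("timing table needs columns:",
                     paste(need, collapse = ", ")),
               "invalid_table_error")
  }
  if (any(t$seconds < 0)) {
    sulba_stop("seconds must be non-negative", "invalid_table_error")
  }
  t
}

# internal: subset a metrics table by optional dataset/architecture filters
filter_table <- function(t, datasets = NULL, architectures = NULL) {
  if (!is.null(datasets)) t <- t[t$dataset %in% datasets, , drop = FALSE]
  if (!is.null(architectures)) {
    t <- t[t$architecture %in% architectures, , drop = FALSE]
  }
  t
}

check_technique <- function(t, technique) {
  if (!technique %in% t$technique) {
    sulba_stop(sprintf("technique '%s' not present in table", technique),
               "missing_technique_error")
  }
}

#' Cumulative score of a technique
#'
#' The sum of every metric value recorded for the technique across the
#' (optionally filtered) datasets, architectures and metrics. This aggregate
#' is the basis of the unified performance ranking: it rewards consistency
#' and damps the influence of single outlier cells.
#'
#' @param t A metrics table (see [validate_metrics_table()]).
#' @param technique Technique name.
#' @param datasets,architectures Optional filters.
#' @return Numeric scalar (0 for an empty filtered subset).
#' @export
cumulative_score <- function(t, technique, datasets = NULL,
                             architectures = NULL) {
  validate_metrics_table(t)
  check_technique(t, technique)
  t <- filter_table(t, datasets, architectures)
  sum(t$value[t$technique == technique])
}

#' Relative improvement over a baseline
#'
#' Cumulative score of the technique minus that of the baseline on the same
#' subset; positive values favour the technique.
#'
#' @inheritParams cumulative_score
#' @param baseline Baseline technique name.
#' @return Numeric scalar, in cumulative-score points.
#' @export
relative_improvement <- function(t, technique, baseline, datasets = NULL,
                                 architectures = NULL) {
  validate_metrics_table(t)
  check_technique(t, technique)
  check_technique(t, baseline)
  cumulative_score(t, technique, datasets, architectures) -
    cumulative_score(t, baseline, datasets, architectures)
}

#' Mean improvement with a 95% confidence interval
#'
#' Relative improvements are computed per group (datasets by default), then
#' averaged; the half-width is `1.96 * sd / sqrt(n)` using the standard error
#' of the mean across groups. With `ci_type = "t"` the Student-t quantile at
#' `n - 1` degrees of freedom replaces 1.96 (more honest at small n).
#'
#' @inheritParams relative_improvement
#' @param grouping `"dataset"` (default) or `"dataset_architecture"` — the
#'   unit over which the mean and its standard error are taken.
#' @param ci_type `"z"` (default, normal-theory 95%) or `"t"`.
#' @return List with `mean`, `half_width`, `n_groups`, `per_group`.
#' @export
mean_improvement_ci <- function(t, technique, baseline,
                                grouping = c("dataset",
                                             "dataset_architecture"),
                                ci_type = c("z", "t")) {
  validate_metrics_table(t)
  grouping <- match.arg(grouping)
  ci_type <- match.arg(ci_type)
  check_technique(t, technique)
  check_technique(t, baseline)
  groups <- if (grouping == "dataset") {
    lapply(unique(t$dataset), function(d) list(datasets = d))
  } else {
    cells <- unique(t[, c("dataset", "architecture")])
    lapply(seq_len(nrow(cells)), function(i) {
      list(datasets = cells$dataset[i], architectures = cells$architecture[i])
    })
  }
  per <- vapply(groups, function(g) {
    relative_improvement(t, technique, baseline,
                         datasets = g$datasets,
                         architectures = g$architectures)
  }, numeric(1))
  n <- length(per)
  if (n < 2L) {
    sulba_stop("need at least 2 groups for a standard error",
               "insufficient_groups_error")
  }
  mult <- if (ci_type == "z") stats::qnorm(0.975) else stats::qt(0.975, n - 1)
  list(mean = mean(per),
       half_width = mult * stats::sd(per) / sqrt(n),
       n_groups = n,
       per_group = per)
}

#' Mean percentage improvement for one architecture
#'
#' Per dataset, the percentage change of the technique's cumulative score
#' over the baseline's (both restricted to the given architecture), averaged
#' across datasets: `mean(100 * (C_tech - C_base) / C_base)`.
#'
#' @inheritParams relative_improvement
#' @param architecture Architecture name to restrict to.
#' @return Numeric scalar (percent).
#' @export
percent_improvement <- function(t, technique, baseline, architecture) {
  validate_metrics_table(t)
  check_technique(t, technique)
  check_technique(t, baseline)
  sub <- filter_table(t, architectures = architecture)
  if (nrow(sub) == 0L) {
    sulba_stop("no rows for the requested architecture",
               "missing_technique_error")
  }
  ds <- unique(sub$dataset)
  pct <- vapply(ds, function(d) {
    cb <- cumulative_score(t, baseline, datasets = d,
                           architectures = architecture)
    ct <- cumulative_score(t, technique, datasets = d,
                           architectures = architecture)
    if (cb == 0) {
      sulba_stop("zero baseline cumulative score for a dataset",
                 "undefined_percentage_error")
    }
    100 * (ct - cb) / cb
  }, numeric(1))
  mean(pct)
}

#' Composite score of a model variant
#'
#' The unweighted arithmetic mean of all metric values recorded for a
#' (technique, architecture) pair — the per-variant summary used in
#' cross-dataset generalization comparisons.
#'
#' @inheritParams cumulative_score
#' @param architecture Architecture / model-variant name.
#' @return Numeric scalar.
#' @export
composite_score <- function(t, technique, architecture) {
  validate_metrics_table(t)
  rows <- t$technique == technique & t$architecture == architecture
  if (!any(rows)) {
    sulba_stop("no metric rows for that technique/architecture",
               "missing_data_error")
  }
  mean(t$value[rows])
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the absolute mean — a dimensionless
#' dispersion measure; here used to quantify how stable a technique's
#' composite scores are across architectures. Both the plain ratio and
#' ratio x 100 are in common circulation; this returns the plain ratio.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return Non-negative scalar.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    sulba_stop("need at least 2 values", "undefined_cv_error")
  }
  m <- mean(values)
  if (m == 0) {
    sulba_stop("coefficient of variation undefined for zero mean",
               "undefined_cv_error")
  }
  stats::sd(values) / abs(m)
}

#' Two-sided paired t-test
#'
#' Tests whether the mean of the paired differences `a - b` is zero.
#' All-zero differences are a degenerate case (no variance): by convention
#' the result is `t = 0`, `p = 1`, flagged `degenerate`.
#'
#' @param a,b Equal-length numeric vectors of paired observations (n >= 2).
#' @param alpha Significance level for the convenience flag (default 0.05).
#' @return List with `t_statistic`, `df`, `p_value`, `significant`,
#'   `degenerate`.
#' @export
paired_ttest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 2L) {
    sulba_stop("a and b must be equal-length with n >= 2",
               "invalid_pairs_error")
  }
  d <- a - b
  if (all(d == 0) || stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t_statistic = 0, df = length(d) - 1L, p_value = 1,
                  significant = FALSE, degenerate = TRUE))
    }
    # constant nonzero differences: infinite t, p -> 0
    return(list(t_statistic = sign(mean(d)) * Inf, df = length(d) - 1L,
                p_value = 0, significant = TRUE, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       significant = tt$p.value <= alpha,
       degenerate = FALSE)
}

#' Training-time overhead of a technique
#'
#' Sums, over experiments, the difference between the technique's total
#' per-epoch seconds and the baseline's. Both techniques must cover the same
#' experiments with the same epoch grids.
#'
#' @param t A timing table (see [read_timing_table()]).
#' @param technique,baseline Technique names.
#' @return Overhead in seconds (negative if the technique is faster).
#' @export
overhead <- function(t, technique, baseline) {
  for (tech in c(technique, baseline)) {
    if (!tech %in% t$technique) {
      sulba_stop(sprintf("technique '%s' not present in timing table", tech),
                 "missing_technique_error")
    }
  }
  a <- t[t$technique == technique, , drop = FALSE]
  b <- t[t$technique == baseline, , drop = FALSE]
  key_a <- sort(paste(a$experiment, a$epoch, sep = "\r"))
  key_b <- sort(paste(b$experiment, b$epoch, sep = "\r"))
  if (!identical(key_a, key_b)) {
    sulba_stop("technique and baseline cover different experiment/epoch grids",
               "coverage_mismatch_error")
  }
  sum(a$seconds) - sum(b$seconds)
}

#' Per-technique timing overhead and significance
#'
#' For every non-baseline technique in a timing table, computes the total
#' overhead versus the baseline and — when at least two experiments are
#' available — a paired t-test of per-experiment total seconds (technique vs
#' baseline, paired by experiment).
#'
#' @param t A timing table (see [read_timing_table()]).
#' @param baseline Baseline technique name.
#' @return Data.frame with columns `technique`, `overhead_seconds`,
#'   `t_statistic`, `p_value`, `significant`.
#' @export
timing_analysis <- function(t, baseline) {
  if (!baseline %in% t$technique) {
    sulba_stop(sprintf("technique '%s' not present in timing table",
                       baseline),
               "missing_technique_error")
  }
  techs <- setdiff(unique(t$technique), baseline)
  per_exp <- function(tech) {
    sub <- t[t$technique == tech, , drop = FALSE]
    tapply(sub$seconds, sub$experiment, sum)
  }
  base_totals <- per_exp(baseline)
  rows <- lapply(techs, function(tech) {
    ov <- overhead(t, tech, baseline)
    totals <- per_exp(tech)[names(base_totals)]
    if (length(base_totals) >= 2L) {
      tt <- paired_ttest(as.numeric(totals), as.numeric(base_totals))
      data.frame(technique = tech, overhead_seconds = ov,
                 t_statistic = tt$t_statistic, p_value = tt$p_value,
                 significant = tt$significant, stringsAsFactors = FALSE)
    } else {
      data.frame(technique = tech, overhead_seconds = ov,
                 t_statistic = NA_real_, p_value = NA_real_,
                 significant = NA, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the unified technique ranking
#'
#' Computes, per technique: the cumulative score, the relative improvement
#' over the baseline, the mean per-dataset improvement with its 95% CI
#' half-width, per-architecture mean percentage improvements, and the
#' coefficient of variation of composite scores across architectures (both
#' as a ratio and x 100). Techniques are ranked by cumulative score,
#' descending; ties share the better rank (competition ranking).
#'
#' @param t A metrics table.
#' @param baseline Baseline technique name (ranked like any other, with
#'   improvement 0).
#' @param ci_type Passed to [mean_improvement_ci()].
#' @return A data.frame of class `ranking_report`, one row per technique,
#'   ordered by rank.
#' @export
build_ranking <- function(t, baseline, ci_type = "z") {
  validate_metrics_table(t)
  check_technique(t, baseline)
  techniques <- unique(t$technique)
  archs <- unique(t$architecture)
  n_datasets <- length(unique(t$dataset))

  rows <- lapply(techniques, function(tech) {
    cum <- cumulative_score(t, tech)
    imp <- relative_improvement(t, tech, baseline)
    mi <- if (n_datasets >= 2L) {
      mean_improvement_ci(t, tech, baseline, ci_type = ci_type)
    } else {
      list(mean = imp, half_width = NA_real_)
    }
    comps <- vapply(archs, function(a) composite_score(t, tech, a),
                    numeric(1))
    cv <- if (length(comps) >= 2L && mean(comps) != 0) {
      coefficient_of_variation(comps)
    } else {
      NA_real_
    }
    out <- data.frame(technique = tech,
                      cumulative_score = cum,
                      relative_improvement = imp,
                      mean_improvement = mi$mean,
                      ci_half_width = mi$half_width,
                      cv = cv,
                      cv_percent = 100 * cv,
                      stringsAsFactors = FALSE)
    for (a in archs) {
      out[[paste0("pct_improvement_", a)]] <-
        tryCatch(percent_improvement(t, tech, baseline, a),
                 sulba_error = function(e) NA_real_)
    }
    out
  })
  report <- do.call(rbind, rows)
  # competition ranking: ties share the minimum rank, later ranks skip
  ord <- order(-report$cumulative_score)
  report <- report[ord, , drop = FALSE]
  report$rank <- rank(-report$cumulative_score, ties.method = "min")
  rownames(report) <- NULL
  class(report) <- c("ranking_report", "data.frame")
  report
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("Technique ranking (by cumulative score)\n")
  shown <- x[, c("rank", "technique", "cumulative_score",
                 "relative_improvement", "mean_improvement",
                 "ci_half_width", "cv")]
  print.data.frame(shown, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Write a ranking report to CSV and/or JSON
#'
#' @param report A `ranking_report` from [build_ranking()].
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the report.
#' @export
write_ranking_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(report), json_path, dataframe = "rows",
                         digits = NA, na = "null")
  }
  invisible(report)
}
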