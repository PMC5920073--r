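#' Line-level summary of replicate measurements
#'
#' Mean and sample standard deviation (n - 1 denominator) of replicate
#' values for one breeding line and one metric. The SD is reported missing
#' for a single replicate, never zero.
#'
#' @param values numeric replicate measurements (length >= 1).
#' @param line_id,group,metric identifying tags carried into the output.
#' @return One-row data frame: `line_id`, `group`, `metric`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_line <- function(values, line_id = NA_character_,
                           group = NA_character_, metric = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    stop("need at least one non-missing replicate value")
  data.frame(line_id = line_id, group = group, metric = metric,
             n = length(values), mean = mean(values),
             sd = if (length(values) >= 2) sd(values) else NA_real_)
}

#' Compare high-oil and low-oil groups on line means
#'
#' Group means are unweighted means of the per-line means; the two groups
#' are compared with a Welch (unequal-variance) two-sample t test, or an
#' exact permutation test on the difference of group means when
#' `method = "permutation"`.
#'
#' @param ho,lo per-line values for the two groups: numeric vectors of line
#'   means, or data frames from [summarize_line()] (the `mean` column is
#'   used).
#' @param metric metric name carried into the output.
#' @param method `"welch"` or `"permutation"`.
#' @return One-row data frame: `metric`, `n_ho`, `n_lo`, `mean_ho`,
#'   `mean_lo`, `diff` (HO - LO), `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(ho, lo, metric = NA_character_,
                           method = c("welch", "permutation")) {
  method <- match.arg(method)
  ho <- line_means(ho)
  lo <- line_means(lo)
  if (length(ho) == 0 || length(lo) == 0)
    stop("both groups need at least one line")
  mean_ho <- mean(ho)
  mean_lo <- mean(lo)
  if (method == "welch") {
    if (length(ho) < 2 || length(lo) < 2)
      stop("the Welch test needs at least two lines per group")
    tt <- t.test(ho, lo, var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    pooled <- c(ho, lo)
    n1 <- length(ho)
    obs <- mean_ho - mean_lo
    splits <- combn(length(pooled), n1)
    diffs <- apply(splits, 2, function(i)
      mean(pooled[i]) - mean(pooled[-i]))
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    stat <- obs
  }
  data.frame(metric = metric, n_ho = length(ho), n_lo = length(lo),
             mean_ho = mean_ho, mean_lo = mean_lo,
             diff = mean_ho - mean_lo, statistic = stat, p_value = p,
             method = method)
}

line_means <- function(x) {
  if (is.data.frame(x)) return(as.numeric(x$mean))
  as.numeric(x)
}

#' Export line summaries and group comparisons as CSV
#'
#' Writes `line_summaries.csv` and `group_comparison.csv` (and, when
#' supplied, a violin-ready `sizes_long.csv`) into `dir` with a
#' deterministic row order (group, line, metric), so repeat runs are
#' byte-identical.
#'
#' @param summaries data frame of stacked [summarize_line()] rows.
#' @param comparisons data frame of stacked [compare_groups()] rows.
#' @param dir output directory (created if needed).
#' @param sizes_long optional long-format droplet size table.
#' @return `dir`, invisibly.
#' @export
export_reports <- function(summaries, comparisons, dir, sizes_long = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(summaries))
    summaries <- summaries[order(summaries$group, summaries$line_id,
                                 summaries$metric), , drop = FALSE]
  if (nrow(comparisons))
    comparisons <- comparisons[order(comparisons$metric), , drop = FALSE]
  write.csv(summaries, file.path(dir, "line_summaries.csv"),
            row.names = FALSE)
  write.csv(comparisons, file.path(dir, "group_comparison.csv"),
            row.names = FALSE)
  if (!is.null(sizes_long))
    write.csv(sizes_long, file.path(dir, "sizes_long.csv"),
              row.names = FALSE)
  invisible(dir)
}
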