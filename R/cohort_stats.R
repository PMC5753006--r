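# Cohort-level aggregation of quality reports and the pairwise method
# comparison: Wilcoxon signed-rank over each quality measure and each pair of
# registration methods (7 measures x 3 pairs = 21 paired tests for a
# three-method design).

#' Assemble a cohort metric table
#'
#' @param reports list of `quality_report` objects.
#' @param subject,method character vectors parallel to `reports`.
#' @return data.frame with columns `subject`, `method` and the seven quality
#'   measures, one row per evaluated (subject, method).
#' @export
cohort_table <- function(reports, subject, method) {
  stopifnot(length(reports) == length(subject),
            length(reports) == length(method))
  rows <- lapply(reports, as.data.frame)
  cbind(data.frame(subject = as.character(subject),
                   method = as.character(method),
                   stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

check_cohort_table <- function(table) {
  need <- c("subject", "method", quality_measures)
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop_data(paste("cohort table is missing columns:",
                    paste(missing, collapse = ", ")))
  }
  tab <- table(table$subject, table$method)
  if (any(tab != 1L)) {
    stop_data("paired design violated: every subject must appear exactly once per method")
  }
  invisible(table)
}

#' Per-method mean and standard deviation of each quality measure
#'
#' @param table cohort data.frame as produced by [cohort_table()].
#' @return data.frame with one row per (method, measure): `mean`, `sd`
#'   (sample SD, n - 1 denominator) and `n`.
#' @export
summarize_cohort <- function(table) {
  check_cohort_table(table)
  methods <- sort(unique(table$method))
  out <- expand.grid(method = methods, measure = quality_measures,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean <- NA_real_; out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    x <- table[table$method == out$method[r], out$measure[r]]
    if (length(x) < 2L) stop_data("summary needs at least 2 subjects per method")
    out$n[r] <- length(x)
    out$mean[r] <- mean(x)
    out$sd[r] <- stats::sd(x)
  }
  out[order(out$measure, out$method), c("measure", "method", "n", "mean", "sd")]
}

# Exact null distribution of the signed-rank statistic W+ over doubled
# (hence integer) midranks: probability vector over W+ = 0 .. sum(ranks),
# built by convolution. Each rank contributes (1 + x^r)/2.
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1L)
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(total + 1L - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Classical Wilcoxon procedure: zero differences are dropped (Wilcoxon's
#' rule), tied absolute differences receive midranks, and the statistic is
#' the sum of ranks of positive differences. For n <= `exact_max` pairs
#' (after zero removal) the two-sided p-value is exact, computed from the
#' full null distribution of the statistic over all sign assignments
#' (`p = min(1, 2 min(P(W <= w), P(W >= w)))`); above that a normal
#' approximation with tie correction and continuity correction is used.
#' If every difference is zero the test is degenerate and `p = 1` is
#' returned by convention.
#'
#' @param x,y paired numeric samples of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (W+), `p_value`, `n_used` (pairs after zero
#'   removal) and `exact` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  if (length(x) < 1L) stop_data("need at least one pair")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_data("non-finite values")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    null <- signed_rank_null(as.integer(round(2 * r)))
    w2 <- as.integer(round(2 * w))
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = w, p_value = p, n_used = n, exact = exact)
}

#' Pairwise method comparison over all quality measures
#'
#' Runs a paired Wilcoxon signed-rank test for every quality measure and
#' every pair of registration methods in the cohort table. For a full
#' three-method design this is 7 measures x 3 method pairs = 21 tests.
#' No multiple-testing correction is applied by default; `adjust = "holm"`
#' applies a Holm correction before flagging significance.
#'
#' @param table cohort data.frame (see [cohort_table()]); every subject must
#'   be evaluated under every method.
#' @param alpha significance level for the `significant` flag.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per (measure, method pair): `measure`,
#'   `method_a`, `method_b`, `statistic`, `p_value`, `significant`.
#' @export
compare_methods <- function(table, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  check_cohort_table(table)
  methods <- sort(unique(table$method))
  if (length(methods) < 2L) stop_data("need at least two methods to compare")
  pairs <- utils::combn(methods, 2L)
  out <- expand.grid(measure = quality_measures,
                     pair = seq_len(ncol(pairs)),
                     stringsAsFactors = FALSE)
  out$method_a <- pairs[1L, out$pair]
  out$method_b <- pairs[2L, out$pair]
  out$statistic <- NA_real_; out$p_value <- NA_real_
  table <- table[order(table$subject), ]
  for (rix in seq_len(nrow(out))) {
    xa <- table[table$method == out$method_a[rix], out$measure[rix]]
    xb <- table[table$method == out$method_b[rix], out$measure[rix]]
    res <- wilcoxon_signed_rank(xa, xb)
    out$statistic[rix] <- res$statistic
    out$p_value[rix] <- res$p_value
  }
  padj <- if (adjust == "holm") stats::p.adjust(out$p_value, "holm") else out$p_value
  out$significant <- padj < alpha
  out$pair <- NULL
  out[, c("measure", "method_a", "method_b", "statistic", "p_value", "significant")]
}
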