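# Statistical stage over subjects x timepoints cohort tables: descriptives,
# one-way repeated-measures ANOVA, Holm-Sidak step-down pairwise comparisons,
# Pearson correlation, simple linear regression, and the minute-1 intrinsic
# variability correlation analysis.

#' Subjects x timepoints cohort table
#'
#' @param values Numeric matrix (or coercible data frame), subjects in rows,
#'   timepoints in columns; `NA` marks missing.
#' @param subjects,timepoints Optional row/column labels; taken from dimnames
#'   when absent.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(values, subjects = NULL, timepoints = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(subjects)) {
    subjects <- rownames(m)
    if (is.null(subjects)) subjects <- sprintf("s%02d", seq_len(nrow(m)))
  }
  if (is.null(timepoints)) {
    timepoints <- colnames(m)
    if (is.null(timepoints)) timepoints <- sprintf("t%d", seq_len(ncol(m)))
  }
  dimnames(m) <- list(subjects, timepoints)
  if (any(is.infinite(m))) stop("cohort values must be finite or NA")
  structure(list(values = m, subjects = subjects, timepoints = timepoints),
            class = "cohort_table")
}

#' Pivot a tidy (subject, timepoint, value) data frame to a cohort table
#'
#' @param df Data frame with columns `subject`, `timepoint`, `value` (or the
#'   first three columns in that role).
#' @return A [cohort_table()]; timepoints keep first-appearance order.
#' @export
as_cohort_table <- function(df) {
  subject <- as.character(df[[1L]])
  timepoint <- as.character(df[[2L]])
  value <- as.numeric(df[[3L]])
  subs <- unique(subject)
  tps <- unique(timepoint)
  m <- matrix(NA_real_, length(subs), length(tps), dimnames = list(subs, tps))
  m[cbind(match(subject, subs), match(timepoint, tps))] <- value
  cohort_table(m)
}

#' Per-timepoint descriptive statistics
#'
#' @param table A [cohort_table()].
#' @return Data frame with `timepoint`, `n`, `mean`, `sd` (n-1 denominator),
#'   `sem` (= sd/sqrt(n)); `sd`/`sem` are `NA` when n = 1.
#' @export
descriptives <- function(table) {
  m <- table$values
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    data.frame(
      timepoint = table$timepoints[j], n = n,
      mean = if (n >= 1) mean(x) else NA_real_,
      sd = if (n >= 2) stats::sd(x) else NA_real_,
      sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition: time effect with k-1 df tested
#' against the subject-by-time residual with (n-1)(k-1) df. Subjects with any
#' missing timepoint are excluded listwise (reported in `n_excluded`). No
#' sphericity correction is applied by default; Greenhouse-Geisser is
#' available via `gg_correction = TRUE`.
#'
#' @param table A [cohort_table()].
#' @param gg_correction Apply the Greenhouse-Geisser epsilon to the F test's
#'   degrees of freedom (default `FALSE`).
#' @return List with `F`, `df_effect`, `df_error`, `p`, `n` (complete
#'   subjects), `k`, `n_excluded`, `degenerate` (`TRUE` when the residual
#'   variance is zero while the time effect is not), and `epsilon` when
#'   corrected.
#' @export
rm_anova <- function(table, gg_correction = FALSE) {
  m <- table$values
  complete <- stats::complete.cases(m)
  n_excluded <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("repeated-measures ANOVA needs >= 2 complete subjects and >= 2 timepoints")

  df <- data.frame(
    value = as.vector(m),
    timepoint = factor(rep(colnames(m), each = n), levels = colnames(m)),
    subject = factor(rep(rownames(m), times = k))
  )
  # additive two-way fixed fit: its time stratum reproduces the classical
  # one-way within-subject F (MS_time over the subject-by-time residual)
  fit <- stats::aov(value ~ timepoint + subject, data = df)
  tab <- summary(fit)[[1L]]
  ss_time <- tab["timepoint", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df_effect <- k - 1
  df_error <- (n - 1) * (k - 1)
  ms_time <- ss_time / df_effect
  ms_err <- ss_err / df_error

  tol <- 1e-12 * max(ss_time, ss_err, 1)
  out <- list(df_effect = df_effect, df_error = df_error, n = n, k = k,
              n_excluded = n_excluded, degenerate = FALSE)
  if (ss_time <= tol) {            # no time effect at all (even if residual 0)
    out$F <- 0; out$p <- 1
  } else if (ms_err <= tol) {      # perfect time effect, zero residual noise
    out$F <- Inf; out$p <- 0; out$degenerate <- TRUE
  } else {
    out$F <- ms_time / ms_err
    d1 <- df_effect; d2 <- df_error
    if (gg_correction) {
      eps <- gg_epsilon(m)
      out$epsilon <- eps
      d1 <- d1 * eps; d2 <- d2 * eps
    }
    out$p <- stats::pf(out$F, d1, d2, lower.tail = FALSE)
  }
  out
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix.
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  SC <- C %*% S %*% C
  sum(diag(SC))^2 / ((k - 1) * sum(SC^2))
}

#' Holm-Sidak step-down multiple comparisons
#'
#' Raw p-values are sorted ascending; the i-th smallest of m is tested at the
#' Sidak level `1 - (1 - alpha)^(1/(m - i + 1))`, and once one comparison
#' fails all larger ones fail. Adjusted p-values are
#' `1 - (1 - p)^(m - i + 1)`, made monotone nondecreasing and capped at 1.
#' Significance is reported at the two tiers used in figure annotation
#' (alpha and 0.001).
#'
#' @param raw_ps Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Familywise error level (default 0.05).
#' @param labels Optional comparison labels.
#' @return Data frame (original input order) with `comparison`, `raw_p`,
#'   `step_alpha`, `adjusted_p`, `significant` (at `alpha`),
#'   `significant_001` (at 0.001).
#' @export
holm_sidak <- function(raw_ps, alpha = 0.05, labels = NULL) {
  m <- length(raw_ps)
  if (m == 0L) {
    return(data.frame(comparison = character(0), raw_p = numeric(0),
                      step_alpha = numeric(0), adjusted_p = numeric(0),
                      significant = logical(0), significant_001 = logical(0)))
  }
  if (any(raw_ps < 0 | raw_ps > 1)) stop("raw p-values must lie in [0, 1]")
  if (is.null(labels)) labels <- sprintf("cmp%d", seq_len(m))
  o <- order(raw_ps)
  ps <- raw_ps[o]
  steps <- m - seq_len(m) + 1            # m, m-1, ..., 1
  step_alpha <- 1 - (1 - alpha)^(1 / steps)
  pass <- ps <= step_alpha
  if (any(!pass)) pass[seq_len(m) >= which(!pass)[1L]] <- FALSE
  adj <- pmin(1, cummax(1 - (1 - ps)^steps))
  res <- data.frame(
    comparison = labels[o], raw_p = ps, step_alpha = step_alpha,
    adjusted_p = adj, significant = pass,
    significant_001 = adj <= 0.001, stringsAsFactors = FALSE)
  res <- res[order(o), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Paired-t comparisons of timepoints against a reference, Holm-Sidak adjusted
#'
#' The comparison family used for figure annotation: every timepoint against
#' a reference column (e.g. baseline, or the start of low-flow support),
#' tested by paired t-tests with Holm-Sidak step-down adjustment.
#'
#' @param table A [cohort_table()].
#' @param reference Reference timepoint label.
#' @param alpha Familywise error level (default 0.05).
#' @return The [holm_sidak()] data frame, labelled "tp vs reference".
#' @export
pairwise_vs_reference <- function(table, reference, alpha = 0.05) {
  if (!reference %in% table$timepoints) {
    stop(sprintf("reference timepoint '%s' not in table", reference))
  }
  others <- setdiff(table$timepoints, reference)
  ref <- table$values[, reference]
  ps <- vapply(others, function(tp) {
    x <- table$values[, tp]
    ok <- !is.na(x) & !is.na(ref)
    stats::t.test(x[ok], ref[ok], paired = TRUE)$p.value
  }, numeric(1))
  holm_sidak(ps, alpha, labels = paste(others, "vs", reference))
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return List with `r`, `p` (two-sided, t on n-2 df), `n`.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Ordinary least-squares simple linear regression
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return List with `slope`, `intercept`, `r` (signed correlation), `p`
#'   (slope t test, two-sided, n-2 df), `n`.
#' @export
simple_linregress <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("regression needs >= 3 complete pairs")
  if (stats::sd(x) == 0) stop("predictor is constant")
  fit <- stats::lm(y ~ x)
  # exact fits trip summary.lm's "essentially perfect fit" warning; the
  # degenerate r/p cases are handled explicitly below
  co <- stats::coef(suppressWarnings(summary(fit)))
  slope <- co["x", "Estimate"]
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  p <- if (stats::sd(y) == 0) 1 else co["x", "Pr(>|t|)"]
  list(slope = slope, intercept = co["(Intercept)", "Estimate"],
       r = r, p = p, n = n)
}

#' Intrinsic-variability correlations against an anchor timepoint
#'
#' Correlates every target timepoint's values with the anchor timepoint's
#' across subjects (Pearson, pairwise-complete), quantifying how much of the
#' between-subject spread is a persistent subject-specific level. Errors
#' (e.g. a constant column) are recorded per row without aborting the rest.
#'
#' @param table A [cohort_table()].
#' @param anchor Anchor timepoint label (e.g. minute 1).
#' @param targets Target timepoint labels.
#' @return Data frame with `target`, `r`, `p`, `n`, `error` (`NA` or the
#'   error message).
#' @export
baseline_variability_correlations <- function(table, anchor, targets) {
  if (!anchor %in% table$timepoints) stop("anchor timepoint not in table")
  missing_tp <- setdiff(targets, table$timepoints)
  if (length(missing_tp) > 0) {
    stop(sprintf("target timepoint(s) not in table: %s",
                 paste(missing_tp, collapse = ", ")))
  }
  a <- table$values[, anchor]
  rows <- lapply(targets, function(tp) {
    res <- tryCatch(pearson(a, table$values[, tp]), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(target = tp, r = NA_real_, p = NA_real_, n = NA_integer_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(target = tp, r = res$r, p = res$p, n = res$n,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
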