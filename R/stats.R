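#' Two-tailed unpaired Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. U is reported as the
#' smaller of the two directional statistics, with midrank tie handling. The
#' p-value is exact (full null distribution) when the pooled sample has at
#' most 16 observations and no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections; the path taken is
#' recorded.
#'
#' @param a,b numeric vectors, each with at least one value.
#' @return list with \code{U}, \code{p} (two-tailed), and \code{method}
#'   (\code{"exact"} or \code{"normal_approx"}).
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups must contain at least one value")
  if (any(!is.finite(c(a, b)))) stop("values must be finite")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (n1 + n2 <= 16L) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  if (!is.finite(p)) p <- 1  # fully tied data carry no evidence
  list(U = min(u1, u2), p = min(p, 1),
       method = if (exact) "exact" else "normal_approx")
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector.
#' @return list with \code{mean}, \code{sem} (sample-sd / sqrt(n); \code{NA}
#'   when n < 2), and \code{n}.
#' @examples
#' summarizeValues(c(1, 2, 3))  # mean 2, sem 1/sqrt(3)
#' @export
summarizeValues <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

.significanceStars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

.compareGroups <- function(metric, labA, labB, va, vb) {
  sa <- summarizeValues(va); sb <- summarizeValues(vb)
  mw <- mannWhitney(va, vb)
  data.frame(metric = metric, group_a = labA, group_b = labB,
             n_a = sa$n, n_b = sb$n,
             mean_a = sa$mean, mean_b = sb$mean,
             sem_a = sa$sem, sem_b = sb$sem,
             U = mw$U, p = mw$p, significant = mw$p < 0.05,
             method = mw$method, stars = .significanceStars(mw$p),
             stringsAsFactors = FALSE)
}

#' Dose-response group comparisons for one metric
#'
#' Builds the standard comparison table for a two-cell-type dose series: for
#' each cell type, every treated dose against that cell type's untreated
#' (dose 0) control; plus the two cell types against each other at every
#' matched dose. When a timepoint column is present, comparisons are made
#' within each timepoint. All tests are two-tailed unpaired Mann-Whitney U;
#' group summaries are mean +/- SEM, and significance at alpha = 0.05 is
#' annotated with the conventional star codes.
#'
#' @param records data.frame of per-spheroid records with at least
#'   \code{cell_type}, \code{dose} and the metric column (e.g. the output of
#'   \code{\link{measureScene}} or \code{\link{readResults}}).
#' @param metric name of the metric column to compare (e.g. \code{"IMVIS"},
#'   \code{"BAF"}, \code{"D_mean"}, \code{"I_max"}).
#' @return data.frame with one row per comparison: group labels, sizes,
#'   means, SEMs, U, two-tailed p, significance flag, method, stars.
#' @export
doseResponseTable <- function(records, metric) {
  stopifnot(is.data.frame(records))
  for (col in c("cell_type", "dose", metric))
    if (!col %in% names(records))
      stop(sprintf("records lack required column '%s'", col))
  if (!"timepoint" %in% names(records)) records$timepoint <- 0
  out <- list()
  for (tp in sort(unique(records$timepoint))) {
    rt <- records[records$timepoint == tp, ]
    tpLab <- if (length(unique(records$timepoint)) > 1L)
      sprintf(" @%gh", tp) else ""
    for (ct in sort(unique(rt$cell_type))) {
      rc <- rt[rt$cell_type == ct, ]
      ctrl <- rc[rc$dose == 0, metric]
      if (length(ctrl) == 0L)
        stop(sprintf("no dose-0 control group for cell type '%s'", ct))
      for (d in sort(unique(rc$dose[rc$dose > 0]))) {
        out[[length(out) + 1L]] <- .compareGroups(
          metric,
          sprintf("%s %g uM%s", ct, d, tpLab),
          sprintf("%s untreated%s", ct, tpLab),
          rc[rc$dose == d, metric], ctrl)
      }
    }
    cts <- sort(unique(rt$cell_type))
    if (length(cts) == 2L) {
      for (d in sort(unique(rt$dose))) {
        va <- rt[rt$cell_type == cts[1] & rt$dose == d, metric]
        vb <- rt[rt$cell_type == cts[2] & rt$dose == d, metric]
        if (length(va) && length(vb))
          out[[length(out) + 1L]] <- .compareGroups(
            metric,
            sprintf("%s %g uM%s", cts[1], d, tpLab),
            sprintf("%s %g uM%s", cts[2], d, tpLab),
            va, vb)
      }
    }
  }
  do.call(rbind, out)
}
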