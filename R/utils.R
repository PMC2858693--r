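# Internal helpers shared across modules. Coordinates are 0-based half-open
# throughout the package; conversion to 1-based happens only at GFF export.

#' @importFrom stats pf pchisq quantile sd mad rnorm runif kmeans cor p.adjust
#'   complete.cases setNames aggregate lm anova qnorm
#' @importFrom utils read.delim write.table head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib snepr, .registration = TRUE
NULL

# midpoint of 0-based half-open interval(s)
interval_mid <- function(start, end) (start + end) / 2

# TRUE where [s1,e1) overlaps [s2,e2) by >= 1 bp (vectorized over first pair)
overlaps_any <- function(s1, e1, s2, e2) {
  if (length(s2) == 0L) return(rep(FALSE, length(s1)))
  ir1 <- IRanges::IRanges(start = s1 + 1L, end = e1)   # 1-based closed for IRanges
  ir2 <- IRanges::IRanges(start = s2 + 1L, end = e2)
  IRanges::overlapsAny(ir1, ir2)
}

# count of intervals in (s2,e2] overlapping each [s1,e1)
count_overlaps0 <- function(s1, e1, s2, e2) {
  ir1 <- IRanges::IRanges(start = s1 + 1L, end = e1)
  ir2 <- IRanges::IRanges(start = s2 + 1L, end = e2)
  IRanges::countOverlaps(ir1, ir2)
}

# Wilson 95% score interval for x successes out of n
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = centre - half, upper = centre + half)
}

# Pearson chi-square on a 2x2 table, continuity correction off by default
chisq_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) return(list(chi2 = NA_real_, p = NA_real_, expected = expected))
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), expected = expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  invisible(df)
}
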