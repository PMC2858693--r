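# Evaluation against simulation truth tables: call recovery and SNEP
# recovery metrics.

#' Recall and precision of nucleosome calls against a truth track
#'
#' A truth nucleosome is recovered if some call on the same chromosome has
#' its midpoint within `tol_bp` of the truth midpoint; a call is correct if
#' it recovers some truth nucleosome. Matching is one-to-one greedy by
#' distance.
#'
#' @param calls data.frame of calls (`chrom start end`).
#' @param truth data.frame of true nucleosomes (`chrom start end`).
#' @param tol_bp midpoint tolerance in bp (default 20).
#' @return list `recall`, `precision`, `n_calls`, `n_truth`,
#'   `median_abs_error` (bp, over matched pairs).
#' @export
call_accuracy <- function(calls, truth, tol_bp = 20) {
  n_match <- 0L
  errs <- numeric(0)
  matched_calls <- 0L
  for (chr in unique(truth$chrom)) {
    tm <- interval_mid(truth$start[truth$chrom == chr], truth$end[truth$chrom == chr])
    cm <- interval_mid(calls$start[calls$chrom == chr], calls$end[calls$chrom == chr])
    if (length(cm) == 0L) next
    used <- rep(FALSE, length(cm))
    for (t_ in sort(tm)) {
      d <- abs(cm - t_)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= tol_bp) {
        used[j] <- TRUE
        n_match <- n_match + 1L
        errs <- c(errs, d[j])
      }
    }
    matched_calls <- matched_calls + sum(used)
  }
  list(recall = n_match / nrow(truth),
       precision = matched_calls / nrow(calls),
       n_calls = nrow(calls), n_truth = nrow(truth),
       median_abs_error = if (length(errs)) stats::median(errs) else NA_real_)
}

#' Recovery of injected SNEPs by the detection pipeline
#'
#' A truth SNEP is recovered if a significant tested pair's BY interval
#' midpoint lies within `tol_bp` of the truth nucleosome midpoint.
#' Direction accuracy and the estimated fold-changes are computed over the
#' recovered set.
#'
#' @param tests `tests` data.frame from [snep_scan()].
#' @param truth_sneps truth SNEP table from the simulator (`chrom start end
#'   direction fold`).
#' @param tol_bp midpoint matching tolerance (default 75, about half a
#'   nucleosome).
#' @return list `sensitivity`, `direction_accuracy`, `median_fold_detected`,
#'   `n_recovered`, `n_truth`, `fold_estimates` (data.frame truth vs
#'   estimated fold for recovered SNEPs).
#' @export
snep_recovery <- function(tests, truth_sneps, tol_bp = 75) {
  sig <- tests[tests$significant, , drop = FALSE]
  sig_mid <- interval_mid(sig$start, sig$end)
  rec <- 0L; dir_ok <- 0L
  folds <- data.frame(fold_true = numeric(), fold_est = numeric(),
                      direction_true = character(), direction_est = character())
  for (i in seq_len(nrow(truth_sneps))) {
    tmid <- interval_mid(truth_sneps$start[i], truth_sneps$end[i])
    cand <- which(sig$chrom == truth_sneps$chrom[i] & abs(sig_mid - tmid) <= tol_bp)
    if (length(cand) == 0L) next
    j <- cand[which.min(abs(sig_mid[cand] - tmid))]
    rec <- rec + 1L
    if (sig$direction[j] == truth_sneps$direction[i]) dir_ok <- dir_ok + 1L
    folds <- rbind(folds, data.frame(
      fold_true = truth_sneps$fold[i], fold_est = sig$fold_change[j],
      direction_true = truth_sneps$direction[i], direction_est = sig$direction[j]))
  }
  list(sensitivity = rec / nrow(truth_sneps),
       direction_accuracy = if (rec > 0) dir_ok / rec else NA_real_,
       median_fold_detected = if (rec > 0) stats::median(folds$fold_est) else NA_real_,
       n_recovered = rec, n_truth = nrow(truth_sneps),
       fold_estimates = folds)
}
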