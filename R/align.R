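# Cross-strain nucleosome alignment: project RM calls onto BY coordinates
# through genome-alignment blocks, then anchor-and-recurse matching of the
# two nucleosome maps.

#' Lift query-genome intervals onto the reference through alignment blocks
#'
#' Intervals fully contained in a single block map by offset
#' (reverse-complement arithmetic for `-` orientation blocks); intervals
#' spanning block boundaries or in unaligned regions get `NA`.
#'
#' @param qry_contig,qry_start,qry_end interval coordinates on the query
#'   genome (0-based half-open).
#' @param blocks alignment blocks ([read_blocks()]).
#' @return data.frame `ref_chrom ref_start ref_end` with NA where the
#'   interval cannot be lifted.
#' @export
lift_intervals_to_ref <- function(qry_contig, qry_start, qry_end, blocks) {
  validate_blocks(blocks)
  n <- length(qry_start)
  out <- data.frame(ref_chrom = rep(NA_character_, n),
                    ref_start = rep(NA_real_, n),
                    ref_end = rep(NA_real_, n))
  if (n == 0L) return(out)
  iv <- GenomicRanges::GRanges(qry_contig, IRanges::IRanges(qry_start + 1L, pmax(qry_end, qry_start + 1L)))
  bl <- GenomicRanges::GRanges(blocks$qry_contig, IRanges::IRanges(blocks$qry_start + 1L, blocks$qry_end))
  hits <- GenomicRanges::findOverlaps(iv, bl, type = "within", select = "first")
  ok <- !is.na(hits)
  if (!any(ok)) return(out)
  b <- blocks[hits[ok], , drop = FALSE]
  qs <- qry_start[ok]; qe <- qry_end[ok]
  plus <- b$orientation == "+"
  rs <- ifelse(plus, b$ref_start + (qs - b$qry_start), b$ref_start + (b$qry_end - qe))
  re <- rs + (qe - qs)
  out$ref_chrom[ok] <- b$ref_chrom
  out$ref_start[ok] <- rs
  out$ref_end[ok] <- re
  out
}

#' Project RM nucleosome calls onto BY coordinates
#'
#' Calls fully inside one alignment block are mapped by offset; calls
#' spanning block boundaries or lying in unaligned regions are dropped
#' (their count is reported via `attr(, "n_dropped")`).
#'
#' @param rm_calls RM nucleosome calls (RM/query coordinates).
#' @param blocks alignment blocks.
#' @return data.frame of calls in BY coordinates with attribute
#'   `n_dropped`.
#' @export
liftover_calls <- function(rm_calls, blocks) {
  lifted <- lift_intervals_to_ref(rm_calls$chrom, rm_calls$start, rm_calls$end, blocks)
  ok <- !is.na(lifted$ref_start)
  out <- rm_calls[ok, , drop = FALSE]
  out$chrom <- lifted$ref_chrom[ok]
  out$start <- lifted$ref_start[ok]
  out$end <- lifted$ref_end[ok]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Distance-minimizing one-to-one assignment of two nucleosome sets
#'
#' Maximum-cardinality, minimum-total-|distance|, order-preserving matching
#' of two sorted midpoint vectors: the assignment used in the recursion
#' step of [align_maps()] between consecutive anchors. For points on a line
#' an order-preserving optimum is a global optimum, so the result equals
#' the exhaustive minimum over all one-to-one matchings of maximal
#' cardinality. Ties are broken toward the leftmost pairing.
#'
#' @param a,b sorted midpoint vectors.
#' @return integer vector, parallel to `a`, giving the index of the matched
#'   element of `b` (NA = unmatched).
#' @export
match_min_cost <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0L) return(integer(0))
  if (n == 0L) return(rep(NA_integer_, m))
  swap <- m < n
  if (swap) { tmp <- a; a <- b; b <- tmp; m <- length(a); n <- length(b) }
  # f[i+1, j+1]: min cost matching first j of b using first i of a
  f <- matrix(Inf, m + 1L, n + 1L)
  f[, 1L] <- 0
  for (i in 1:m) {
    jmax <- min(i, n)
    for (j in 1:jmax) {
      take <- f[i, j] + abs(a[i] - b[j])
      skip <- f[i, j + 1L]
      f[i + 1L, j + 1L] <- min(take, skip)
    }
  }
  # traceback (prefer "take" on ties => leftmost pairing for a)
  map_a <- rep(NA_integer_, m)
  i <- m; j <- n
  while (j > 0L) {
    if (i == j || f[i, j] + abs(a[i] - b[j]) <= f[i, j + 1L]) {
      map_a[i] <- j; i <- i - 1L; j <- j - 1L
    } else {
      i <- i - 1L
    }
  }
  if (!swap) return(map_a)
  # invert: we matched b's elements to a; produce a->b map
  inv <- rep(NA_integer_, length(b))
  matched <- which(!is.na(map_a))
  inv[map_a[matched]] <- matched
  inv
}

#' Align BY and (projected) RM nucleosome maps
#'
#' Anchor pass: pairs whose midpoint distance is below half their average
#' size, i.e. `(len_by + len_rm) / 4`, and which are mutually nearest are
#' marked unambiguously aligned. Recursion: between consecutive anchors the
#' remaining nucleosomes are assigned by the order-preserving one-to-one
#' matching minimizing the sum of midpoint distances. Unmatched BY calls
#' become insertions, unmatched RM calls deletions (with respect to BY).
#' Per-pair state likelihoods `L(aligned) = B_n R_n`,
#' `L(insertion) = B_n R_l`, `L(deletion) = B_l R_n` are computed from the
#' mean merged nucleosome posterior of each strain over the pair footprint
#' when posterior tracks are supplied.
#'
#' @param by_calls BY nucleosome calls.
#' @param rm_calls RM calls already projected to BY coordinates
#'   ([liftover_calls()]).
#' @param by_post,rm_post optional posterior tracks (`chrom position
#'   post_nuc`, BY coordinates) used for the likelihood annotations.
#' @return data.frame of nucleosome pairs: `pair_id chrom status by_start
#'   by_end rm_start rm_end midpoint_distance overlap_fraction_by B_n R_n
#'   B_l R_l L_aligned L_insertion L_deletion category_by category_rm`.
#' @export
align_maps <- function(by_calls, rm_calls, by_post = NULL, rm_post = NULL) {
  res <- list()
  for (chr in union(unique(by_calls$chrom), unique(rm_calls$chrom))) {
    bc <- by_calls[by_calls$chrom == chr, , drop = FALSE]
    rc <- rm_calls[rm_calls$chrom == chr, , drop = FALSE]
    bc <- bc[order(bc$start), , drop = FALSE]
    rc <- rc[order(rc$start), , drop = FALSE]
    res[[length(res) + 1L]] <- align_chrom(bc, rc, chr)
  }
  pairs <- do.call(rbind, res)
  rownames(pairs) <- NULL
  pairs$pair_id <- sprintf("%s_p%05d", pairs$chrom,
                           as.integer(stats::ave(seq_len(nrow(pairs)),
                                                 pairs$chrom, FUN = seq_along)))
  pairs <- annotate_pair_likelihoods(pairs, by_post, rm_post)
  pairs[, c("pair_id", setdiff(names(pairs), "pair_id"))]
}

align_chrom <- function(bc, rc, chr) {
  nb <- nrow(bc); nr <- nrow(rc)
  mk_row <- function(status, bi, ri) {
    data.frame(
      chrom = chr, status = status,
      by_start = if (is.na(bi)) NA_real_ else bc$start[bi],
      by_end = if (is.na(bi)) NA_real_ else bc$end[bi],
      rm_start = if (is.na(ri)) NA_real_ else rc$start[ri],
      rm_end = if (is.na(ri)) NA_real_ else rc$end[ri],
      category_by = if (is.na(bi)) NA_character_ else bc$category[bi],
      category_rm = if (is.na(ri)) NA_character_ else rc$category[ri],
      stringsAsFactors = FALSE)
  }
  rows <- list()
  if (nb > 0L && nr > 0L) {
    bmid <- interval_mid(bc$start, bc$end)
    rmid <- interval_mid(rc$start, rc$end)

    # anchor pass: mutually nearest and closer than half the average size
    nearest_r <- vapply(bmid, function(m) which.min(abs(rmid - m)), integer(1))
    nearest_b <- vapply(rmid, function(m) which.min(abs(bmid - m)), integer(1))
    anchors <- list()
    for (i in seq_len(nb)) {
      j <- nearest_r[i]
      if (nearest_b[j] == i) {
        lim <- (bc$end[i] - bc$start[i] + rc$end[j] - rc$start[j]) / 4
        if (abs(bmid[i] - rmid[j]) < lim) anchors[[length(anchors) + 1L]] <- c(i, j)
      }
    }
    # keep anchors consistent with genomic order on both sides
    anc <- matrix(0L, 0L, 2L)
    last_j <- 0L
    for (p in anchors) if (p[2] > last_j) { anc <- rbind(anc, p); last_j <- p[2] }

    matched_b <- rep(NA_integer_, nb)
    if (nrow(anc)) matched_b[anc[, 1]] <- anc[, 2]

    # recursion between consecutive anchors (and the flanks)
    bounds_i <- c(0L, anc[, 1], nb + 1L)
    bounds_j <- c(0L, anc[, 2], nr + 1L)
    for (k in seq_len(length(bounds_i) - 1L)) {
      bi <- seq_len(nb)[seq_len(nb) > bounds_i[k] & seq_len(nb) < bounds_i[k + 1L]]
      rj <- seq_len(nr)[seq_len(nr) > bounds_j[k] & seq_len(nr) < bounds_j[k + 1L]]
      if (length(bi) == 0L) next
      mp <- match_min_cost(bmid[bi], rmid[rj])
      matched_b[bi] <- rj[mp]
    }

    used_r <- rep(FALSE, nr)
    for (i in seq_len(nb)) {
      j <- matched_b[i]
      if (is.na(j)) {
        rows[[length(rows) + 1L]] <- mk_row("insertion", i, NA)
      } else {
        used_r[j] <- TRUE
        rows[[length(rows) + 1L]] <- mk_row("aligned", i, j)
      }
    }
    for (j in which(!used_r)) rows[[length(rows) + 1L]] <- mk_row("deletion", NA, j)
  } else if (nb > 0L) {
    for (i in seq_len(nb)) rows[[length(rows) + 1L]] <- mk_row("insertion", i, NA)
  } else if (nr > 0L) {
    for (j in seq_len(nr)) rows[[length(rows) + 1L]] <- mk_row("deletion", NA, j)
  }
  if (length(rows) == 0L) {
    out <- mk_row("aligned", NA, NA)[0L, , drop = FALSE]
    out$midpoint_distance <- numeric(0)
    out$overlap_fraction_by <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$midpoint_distance <- abs(interval_mid(out$by_start, out$by_end) -
                                 interval_mid(out$rm_start, out$rm_end))
  ov <- pmax(0, pmin(out$by_end, out$rm_end) - pmax(out$by_start, out$rm_start))
  out$overlap_fraction_by <- ov / (out$by_end - out$by_start)
  out[order(pmin(out$by_start, out$rm_start, na.rm = TRUE)), , drop = FALSE]
}

annotate_pair_likelihoods <- function(pairs, by_post, rm_post) {
  n <- nrow(pairs)
  pairs$B_n <- pairs$R_n <- rep(NA_real_, n)
  if (!is.null(by_post) && !is.null(rm_post)) {
    lo <- pmin(pairs$by_start, pairs$rm_start, na.rm = TRUE)
    hi <- pmax(pairs$by_end, pairs$rm_end, na.rm = TRUE)
    for (chr in unique(pairs$chrom)) {
      pi <- which(pairs$chrom == chr)
      bp_ <- by_post[by_post$chrom == chr, , drop = FALSE]
      rp <- rm_post[rm_post$chrom == chr, , drop = FALSE]
      pairs$B_n[pi] <- mean_in_intervals(bp_$position, bp_$post_nuc, lo[pi], hi[pi])
      pairs$R_n[pi] <- mean_in_intervals(rp$position, rp$post_nuc, lo[pi], hi[pi])
    }
  }
  pairs$B_l <- 1 - pairs$B_n
  pairs$R_l <- 1 - pairs$R_n
  pairs$L_aligned <- pairs$B_n * pairs$R_n
  pairs$L_insertion <- pairs$B_n * pairs$R_l
  pairs$L_deletion <- pairs$B_l * pairs$R_n
  pairs
}

# mean of y over positions in [lo, hi) for each interval
mean_in_intervals <- function(pos, y, lo, hi) {
  ord <- order(pos)
  pos <- pos[ord]; y <- y[ord]
  cs <- cumsum(ifelse(is.na(y), 0, y))
  cn <- cumsum(!is.na(y))
  i1 <- findInterval(lo, pos, left.open = TRUE) + 1L  # first pos >= lo
  i2 <- findInterval(hi, pos, left.open = TRUE)       # last pos < hi
  out <- rep(NA_real_, length(lo))
  ok <- !is.na(lo) & !is.na(hi) & i2 >= i1
  prev <- i1[ok] - 1L
  base_s <- base_n <- rep(0, sum(ok))
  base_s[prev > 0L] <- cs[prev[prev > 0L]]
  base_n[prev > 0L] <- cn[prev[prev > 0L]]
  s <- cs[i2[ok]] - base_s
  k <- cn[i2[ok]] - base_n
  out[ok] <- ifelse(k > 0, s / k, NA_real_)
  out
}

#' Summarize nucleosome map conservation
#'
#' @param pairs output of [align_maps()].
#' @param probs quantile probabilities for the midpoint-distance and
#'   BY-overlap summaries.
#' @return list with `n_aligned`, `n_insertion`, `n_deletion`,
#'   `fraction_aligned` (aligned / all pairs), `distance_quantiles` and
#'   `overlap_quantiles`.
#' @export
conservation_stats <- function(pairs, probs = c(0.25, 0.5, 0.75, 0.8, 0.9)) {
  al <- pairs[pairs$status == "aligned", , drop = FALSE]
  if (nrow(al) == 0L) stop("no aligned pairs", call. = FALSE)
  list(
    n_aligned = nrow(al),
    n_insertion = sum(pairs$status == "insertion"),
    n_deletion = sum(pairs$status == "deletion"),
    fraction_aligned = nrow(al) / nrow(pairs),
    distance_quantiles = stats::quantile(al$midpoint_distance, probs, names = TRUE),
    overlap_quantiles = stats::quantile(al$overlap_fraction_by, probs, names = TRUE)
  )
}

#' Per-window occupancy difference between strains
#'
#' In sliding windows along each chromosome, computes the fraction of
#' nucleosomal DNA per strain as the mean merged nucleosome posterior of the
#' probes in the window, and flags windows in the extreme `flag_quantile`
#' tails of the BY - RM difference. Windows containing an insertion or
#' deletion of `min_indel_bp` or more are excluded.
#'
#' @param by_post,rm_post posterior tracks (`chrom position post_nuc`,
#'   shared BY coordinates).
#' @param polymorphisms polymorphism table used for the indel exclusion.
#' @param window_bp window length (default 2500).
#' @param step_bp window step (default `window_bp`, i.e. tiling).
#' @param min_indel_bp indel size triggering exclusion (default 5).
#' @param flag_quantile two-sided tail probability for flagging (default
#'   1/1000).
#' @return data.frame `chrom start end occ_by occ_rm diff flagged`.
#' @export
occupancy_difference_windows <- function(by_post, rm_post, polymorphisms,
                                         window_bp = 2500, step_bp = window_bp,
                                         min_indel_bp = 5, flag_quantile = 1 / 1000) {
  indels <- polymorphisms[polymorphisms$kind != "SNP" &
                            pmax(polymorphisms$ref_len, polymorphisms$qry_len) >= min_indel_bp, ,
                          drop = FALSE]
  res <- list()
  for (chr in intersect(unique(by_post$chrom), unique(rm_post$chrom))) {
    bp_ <- by_post[by_post$chrom == chr, , drop = FALSE]
    rp <- rm_post[rm_post$chrom == chr, , drop = FALSE]
    lo <- min(bp_$position); hi <- max(bp_$position)
    if (hi - lo < window_bp) next
    starts <- seq(lo, hi - window_bp, by = step_bp)
    occ_by <- mean_in_intervals(bp_$position, bp_$post_nuc, starts, starts + window_bp)
    occ_rm <- mean_in_intervals(rp$position, rp$post_nuc, starts, starts + window_bp)
    ind <- indels[indels$chrom == chr, , drop = FALSE]
    iv <- polymorphism_intervals(ind)
    has_indel <- overlaps_any(starts, starts + window_bp, iv$start, iv$end)
    res[[length(res) + 1L]] <- data.frame(
      chrom = chr, start = starts, end = starts + window_bp,
      occ_by = occ_by, occ_rm = occ_rm, has_indel = has_indel,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[!out$has_indel & !is.na(out$occ_by) & !is.na(out$occ_rm), , drop = FALSE]
  out$has_indel <- NULL
  out$diff <- out$occ_by - out$occ_rm
  qs <- stats::quantile(out$diff, c(flag_quantile, 1 - flag_quantile), names = FALSE)
  out$flagged <- out$diff < qs[1] | out$diff > qs[2]
  rownames(out) <- NULL
  out
}
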