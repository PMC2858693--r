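# Probe preparation: dual-genome probe selection, polymorphism filtering,
# quantile normalization, and SNP-density bookkeeping.

#' Select probes usable in both genomes
#'
#' Retains probes that (i) have a unique perfect match in both the reference
#' (BY) and query (RM) genome, (ii) whose RM match, lifted through the genome
#' alignment blocks onto BY coordinates, lies within `slack_bp` of the BY
#' match start, and (iii) whose BY footprint overlaps no BY/RM polymorphism.
#' Probes whose RM match does not fall entirely inside one alignment block
#' are excluded (block boundaries are indel-adjacent, so the lifted
#' coordinate would be ill-defined).
#'
#' @param by_matches,rm_matches probe maps (see [read_probe_map()]) for the
#'   reference and query genome.
#' @param blocks alignment blocks (see [read_blocks()]).
#' @param polymorphisms polymorphism table (see [read_polymorphisms()]).
#' @param slack_bp maximum distance (bp) between the BY match start and the
#'   lifted RM match start; default 3.
#' @param verbose print exclusion counts.
#' @return character vector of retained probe ids.
#' @export
select_dual_probes <- function(by_matches, rm_matches, blocks, polymorphisms,
                               slack_bp = 3, verbose = FALSE) {
  validate_blocks(blocks)
  by_u <- by_matches[by_matches$n_matches == 1L, , drop = FALSE]
  rm_u <- rm_matches[rm_matches$n_matches == 1L, , drop = FALSE]

  only_one <- length(union(by_matches$probe_id, rm_matches$probe_id)) -
    length(intersect(by_u$probe_id, rm_u$probe_id))
  shared <- intersect(by_u$probe_id, rm_u$probe_id)
  by_u <- by_u[match(shared, by_u$probe_id), , drop = FALSE]
  rm_u <- rm_u[match(shared, rm_u$probe_id), , drop = FALSE]

  # lift RM match interval to BY coordinates through the blocks
  lifted <- lift_intervals_to_ref(rm_u$chrom, rm_u$start, rm_u$start + rm_u$length, blocks)
  within_slack <- !is.na(lifted$ref_start) &
    lifted$ref_chrom == by_u$chrom &
    abs(lifted$ref_start - by_u$start) <= slack_bp

  # polymorphism overlap on the BY footprint
  poly_iv <- polymorphism_intervals(polymorphisms)
  hits_poly <- rep(FALSE, nrow(by_u))
  for (chr in unique(by_u$chrom)) {
    i <- which(by_u$chrom == chr)
    j <- which(poly_iv$chrom == chr)
    hits_poly[i] <- overlaps_any(by_u$start[i], by_u$start[i] + by_u$length[i],
                                 poly_iv$start[j], poly_iv$end[j])
  }

  keep <- within_slack & !hits_poly
  if (verbose) {
    message(sprintf("dual-probe selection: %d single-genome/ambiguous, %d outside slack/blocks, %d polymorphic, %d retained",
                    only_one, sum(!within_slack), sum(within_slack & hits_poly), sum(keep)))
  }
  by_u$probe_id[keep]
}

# BY-projected interval of each polymorphism: SNPs and insertions cover their
# reference footprint; deletions (no reference bases) cover the 1 bp junction
# so a probe spanning the breakpoint is flagged.
polymorphism_intervals <- function(polymorphisms) {
  if (nrow(polymorphisms) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  len <- pmax(polymorphisms$ref_len, 1L)
  data.frame(chrom = polymorphisms$chrom,
             start = polymorphisms$pos,
             end = polymorphisms$pos + len)
}

#' Quantile-normalize an intensity matrix
#'
#' All arrays are normalized together: the value at rank r in every array is
#' replaced by the mean of the rank-r values across arrays. Missing values
#' are excluded from the ranking and restored as missing; when arrays have
#' unequal numbers of observed values the reference distribution is read off
#' at the corresponding proportion points (type-7 quantiles), which reduces
#' to the exact rank-mean when counts are equal. Ties keep their input order
#' so the multiset of normalized values is identical across (complete)
#' arrays.
#'
#' @param x an [intensity_matrix()].
#' @param log2_input if `TRUE`, values are linear-scale and `log2` is applied
#'   first (values must be strictly positive).
#' @return an `intensity_matrix` with normalized values.
#' @export
quantile_normalize <- function(x, log2_input = FALSE) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  if (log2_input) {
    if (any(v <= 0, na.rm = TRUE))
      stop("linear-scale intensities must be strictly positive before log2", call. = FALSE)
    v <- log2(v)
  }
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0L))
    stop("array with all-missing values: ",
         paste(colnames(v)[n_obs == 0L], collapse = ", "), call. = FALSE)

  sorted <- lapply(seq_len(ncol(v)), function(j) sort(v[, j], na.last = NA))
  equal_n <- length(unique(n_obs)) == 1L
  if (equal_n) {
    ref <- rowMeans(do.call(cbind, sorted))
  }
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- !is.na(v[, j])
    r <- rank(v[obs, j], ties.method = "first")
    if (equal_n) {
      out[obs, j] <- ref[r]
    } else {
      p <- (r - 1) / (n_obs[j] - 1)
      vals <- rowMeans(vapply(sorted, function(s) stats::quantile(s, p, type = 7, names = FALSE),
                              numeric(length(p))))
      out[obs, j] <- vals
    }
  }
  intensity_matrix(out, x$manifest)
}

#' SNP density in nucleosomal versus linker DNA
#'
#' The genome covered by `span` is partitioned into a nucleosomal compartment
#' (union of call intervals) and a linker compartment (the remainder);
#' SNP-kind polymorphisms are counted in each and divided by compartment
#' length.
#'
#' @param polymorphisms polymorphism table; only rows with `kind == "SNP"`
#'   are used.
#' @param calls nucleosome calls defining the nucleosomal compartment.
#' @param span data.frame `chrom start end` giving the covered genome;
#'   defaults to the per-chromosome range of the calls.
#' @return named numeric vector `c(nucleosomal =, linker =)` in SNPs per kb.
#' @export
snp_density_by_compartment <- function(polymorphisms, calls, span = NULL) {
  snps <- polymorphisms[polymorphisms$kind == "SNP", , drop = FALSE]
  if (is.null(span)) {
    span <- do.call(rbind, lapply(split(calls, calls$chrom), function(d) {
      data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end))
    }))
  }
  nuc_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1L, calls$end)))
  span_gr <- GenomicRanges::GRanges(span$chrom, IRanges::IRanges(span$start + 1L, span$end))
  nuc_gr <- GenomicRanges::intersect(nuc_gr, span_gr)
  link_gr <- GenomicRanges::setdiff(span_gr, nuc_gr)

  len_nuc <- sum(GenomicRanges::width(nuc_gr))
  len_link <- sum(GenomicRanges::width(link_gr))
  if (len_nuc == 0 || len_link == 0)
    stop("zero-length compartment: cannot compute SNP densities", call. = FALSE)

  snp_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos + 1L, snps$pos + 1L))
  in_nuc <- sum(IRanges::overlapsAny(snp_gr, nuc_gr))
  in_link <- sum(IRanges::overlapsAny(snp_gr, link_gr))
  c(nucleosomal = in_nuc / len_nuc * 1000, linker = in_link / len_link * 1000)
}
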