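#' Read a per-strain probe map
#'
#' Tab-separated table with header
#' `probe_id chrom start strand length n_matches`, one row per probe match.
#' Coordinates are 0-based half-open (`start` is the first base of the 25-mer
#' footprint).
#'
#' @param path path to the TSV file.
#' @return data.frame with the columns above.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("probe_id", "chrom", "start", "strand", "length", "n_matches"),
                       "probe map")
  df
}

#' Read an intensity matrix and its array manifest
#'
#' The intensity file is a TSV whose first column is `probe_id` and remaining
#' columns are array ids; the manifest is a TSV
#' `array_id strain assay replicate`. Values may be on linear or log2 scale
#' (see [quantile_normalize()]).
#'
#' @param intensity_path,manifest_path file paths.
#' @return an `intensity_matrix` object (see [intensity_matrix()]).
#' @export
read_intensities <- function(intensity_path, manifest_path) {
  raw <- utils::read.delim(intensity_path, check.names = FALSE, stringsAsFactors = FALSE)
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  stop_if_missing_cols(manifest, c("array_id", "strain", "assay", "replicate"), "manifest")
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- raw[[1]]
  intensity_matrix(values, manifest)
}

#' Construct an intensity matrix container
#'
#' Couples a probe x array matrix of (log2) intensities with the array
#' manifest describing strain, assay type and replicate of each column.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   arrays in columns (colnames = array ids). `NA` marks missing values.
#' @param manifest data.frame with columns `array_id`, `strain` (`"BY"`/`"RM"`),
#'   `assay` (`"nuc"`/`"chip"`), `replicate`; one row per column of `values`.
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, manifest) {
  stop_if_missing_cols(manifest, c("array_id", "strain", "assay", "replicate"), "manifest")
  if (is.null(colnames(values))) colnames(values) <- manifest$array_id
  manifest <- manifest[match(colnames(values), manifest$array_id), , drop = FALSE]
  if (anyNA(manifest$array_id))
    stop("manifest does not describe every column of the intensity matrix", call. = FALSE)
  if (anyDuplicated(manifest[c("strain", "assay", "replicate")]))
    stop("duplicated (strain, assay, replicate) combination in manifest", call. = FALSE)
  structure(list(values = values, manifest = manifest), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d probes x %d arrays (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  print(table(x$manifest$strain, x$manifest$assay))
  invisible(x)
}

#' Read a polymorphism table
#'
#' TSV `kind chrom pos ref_len qry_len` with `kind` in
#' `{SNP, insertion, deletion}`; `pos` is the 0-based reference (BY)
#' position. Insertions are sequence present in BY and absent in RM
#' (`qry_len == 0`); deletions are absent in BY (`ref_len == 0`).
#'
#' @param path path to the TSV file.
#' @return data.frame with the columns above.
#' @export
read_polymorphisms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("kind", "chrom", "pos", "ref_len", "qry_len"), "polymorphism table")
  df
}

#' Read genome alignment blocks
#'
#' TSV `ref_chrom ref_start ref_end qry_contig qry_start qry_end orientation`
#' (show-coords column order, 0-based half-open). Blocks must be ungapped:
#' `ref_end - ref_start == qry_end - qry_start`.
#'
#' @param path path to the TSV file.
#' @return data.frame of blocks.
#' @export
read_blocks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("ref_chrom", "ref_start", "ref_end",
                             "qry_contig", "qry_start", "qry_end", "orientation"), "block table")
  validate_blocks(df)
}

validate_blocks <- function(blocks) {
  if (nrow(blocks) == 0L) stop("alignment block table is empty", call. = FALSE)
  if (any(blocks$ref_end <= blocks$ref_start) || any(blocks$qry_end <= blocks$qry_start))
    stop("malformed alignment block: non-positive length", call. = FALSE)
  if (any((blocks$ref_end - blocks$ref_start) != (blocks$qry_end - blocks$qry_start)))
    stop("alignment blocks must be ungapped (equal ref and qry lengths)", call. = FALSE)
  blocks
}

#' Write nucleosome calls as GFF3
#'
#' One `nucleosome` feature per call with `category`, `posterior` and
#' `n_probes` attributes. Internal 0-based half-open coordinates are
#' converted to GFF 1-based inclusive.
#'
#' @param calls data.frame of nucleosome calls (see [call_nucleosomes()]).
#' @param path output file.
#' @export
write_calls_gff3 <- function(calls, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = "*",
    source = "snepr",
    type = "nucleosome",
    score = round(calls$posterior, 4),
    category = calls$category,
    posterior = round(calls$posterior, 4),
    n_probes = calls$n_probes
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write nucleosome calls as BED6
#'
#' Score column is `round(1000 * posterior)`.
#'
#' @inheritParams write_calls_gff3
#' @export
write_calls_bed <- function(calls, path) {
  df <- data.frame(
    chrom = calls$chrom,
    start = calls$start,
    end = calls$end,
    name = paste0(calls$strain, "_", calls$category, "_", seq_len(nrow(calls))),
    score = round(1000 * calls$posterior),
    strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read nucleosome calls written by [write_calls_gff3()]
#'
#' @param path GFF3 file.
#' @param strain strain label to attach to the calls.
#' @return data.frame of calls (0-based half-open coordinates).
#' @export
read_calls_gff3 <- function(path, strain = NA_character_) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(
    strain = strain,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    category = as.character(gr$category),
    posterior = as.numeric(gr$posterior),
    n_probes = as.integer(gr$n_probes),
    stringsAsFactors = FALSE
  )
}

#' Read a gene model table
#'
#' TSV `gene_id chrom strand tss tes cds_start cds_end` (0-based half-open;
#' `tss`/`tes` are transcript boundaries oriented so that `tss < tes` on the
#' `+` strand and `tss > tes` is not allowed -- orientation is carried by
#' `strand`).
#'
#' @param path path to the TSV file.
#' @return data.frame of gene models.
#' @export
read_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("gene_id", "chrom", "strand", "tss", "tes",
                             "cds_start", "cds_end"), "gene table")
  df
}

#' Read a BED3+name feature set
#'
#' @param path BED file (chrom, start, end, name; 0-based half-open).
#' @param name feature-set name; defaults to the file name.
#' @return list with `name` and `intervals` data.frame.
#' @export
read_feature_bed <- function(path, name = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  list(name = name %||% basename(path), intervals = df[order(df$chrom, df$start), ])
}

#' Read a per-gene score table
#'
#' TSV `gene_id value`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `value`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("gene_id", "value"), "score table")
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
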