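# Truth-annotated synthetic data: two related genomes (SNPs + indels),
# gene-aware nucleosome landscapes with promoter NDRs, dual probe maps and
# replicate intensity matrices with injected acetylation SNEPs. Every output
# is consistent with a single edit script, so all pipeline stages can be
# validated against the truth tables.

#' Simulation configuration
#'
#' Defaults emulate the study design: 4 bp probe tiling of 25-mers, 147 bp
#' nucleosomes with short linkers, promoter nucleosome-depleted regions, 3
#' nucleosome-mapping + 6 ChIP replicates per strain, SNP/indel rates of the
#' BY/RM comparison (about 0.4% SNPs), and quantitative SNEPs of 1.2-1.5
#' fold with the observed direction mix.
#'
#' @param seed RNG seed; all outputs are deterministic given it.
#' @param genome_bp,n_chromosomes genome size (total) and chromosome count.
#' @param snp_rate,indel_rate per-bp event rates.
#' @param indel_len_mean mean indel length (geometric, >= 1).
#' @param genes_per_kb gene density (transcripts per kb).
#' @param probe_len,probe_spacing_bp probe footprint and tiling step.
#' @param nucleosome_len_bp,linker_len_range,ndr_width_bp chromatin
#'   geometry.
#' @param delocalized_frac fraction of nucleosomes simulated as delocalized.
#' @param mean_l,mean_d,mean_w,emission_sd log2 emission parameters of the
#'   linker / delocalized / well-positioned states.
#' @param n_nuc_replicates,n_chip_replicates replicates per strain.
#' @param ac_base,ac_jitter baseline log2 ChIP enrichment of acetylated
#'   nucleosomes and its per-nucleosome jitter (shared between strains).
#' @param snep_count number of injected SNEPs (`NULL` = 9% of nucleosomes).
#' @param snep_fold_range fold-difference range of injected SNEPs.
#' @param snep_byac_frac fraction of SNEPs more acetylated in BY.
#' @param missing_rate per-value missing probability.
#' @param snp_bias log2 signal loss on RM arrays for probes whose footprint
#'   contains a polymorphism (hybridization mismatch).
#' @return list of configuration values (class `sim_config`).
#' @export
sim_config <- function(seed = 1, genome_bp = 200000, n_chromosomes = 2,
                       snp_rate = 0.004, indel_rate = 2e-4, indel_len_mean = 8,
                       genes_per_kb = 0.5, probe_len = 25, probe_spacing_bp = 4,
                       nucleosome_len_bp = 147, linker_len_range = c(15, 25),
                       ndr_width_bp = 140, delocalized_frac = 0.2,
                       mean_l = -1, mean_d = 0.85, mean_w = 1, emission_sd = 0.5,
                       n_nuc_replicates = 3, n_chip_replicates = 6,
                       ac_base = 0.6, ac_jitter = 0.15, snep_count = NULL,
                       snep_fold_range = c(1.2, 1.5), snep_byac_frac = 0.415,
                       missing_rate = 0.01, snp_bias = -1) {
  cfg <- as.list(environment())
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            all(snep_fold_range >= 1), genome_bp > 0, n_chromosomes >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference genome and a derived query genome
#'
#' The query (RM-like) genome is derived from the reference (BY-like) by
#' point substitutions and indels; alignment blocks and the polymorphism
#' table are emitted consistent with the edit script. Insertions are
#' sequence present in the reference and absent from the query; deletions
#' the reverse.
#'
#' @param cfg a [sim_config()].
#' @return list `by_seq`, `rm_seq` (named character vectors of chromosome /
#'   contig sequences), `blocks`, `polymorphisms`, `chrom_lens`, `features`
#'   (rDNA-like interval and Ty-like anchor points for enrichment
#'   analyses).
#' @export
simulate_genomes <- function(cfg) {
  set.seed(cfg$seed)
  chr_len <- rep(floor(cfg$genome_bp / cfg$n_chromosomes), cfg$n_chromosomes)
  chroms <- paste0("chr", utils::as.roman(seq_len(cfg$n_chromosomes)))
  by_seq <- list(); rm_seq <- list()
  blocks <- list(); polys <- list()
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]; len <- chr_len[ci]
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)

    n_ind <- stats::rbinom(1, len, cfg$indel_rate)
    ind_pos <- sort(sample(seq(100, len - 200), n_ind))
    if (n_ind > 1L) ind_pos <- ind_pos[c(TRUE, diff(ind_pos) >= 200)]  # keep indels apart
    n_ind <- length(ind_pos)
    ind_len <- pmin(stats::rgeom(n_ind, 1 / cfg$indel_len_mean) + 1L, 60L)
    ind_type <- sample(c("insertion", "deletion"), n_ind, replace = TRUE)

    n_snp <- stats::rbinom(1, len, cfg$snp_rate)
    snp_pos <- sort(sample.int(len, n_snp) - 1L)
    # no SNPs inside reference-only (insertion) segments or at indel junctions
    if (n_ind > 0) {
      bad <- rep(FALSE, n_snp)
      for (k in seq_len(n_ind)) {
        span <- if (ind_type[k] == "insertion") ind_len[k] else 1L
        bad <- bad | (snp_pos >= ind_pos[k] - 1L & snp_pos < ind_pos[k] + span)
      }
      snp_pos <- snp_pos[!bad]
    }

    # walk the edit script: emit blocks and assemble the query sequence
    qry_chunks <- list(); chr_blocks <- list()
    prev <- 0L; qoff <- 0L
    qry_name <- paste0("sc_", chr)
    emit_block <- function(ref_a, ref_b) {
      if (ref_b > ref_a)
        chr_blocks[[length(chr_blocks) + 1L]] <<- data.frame(
          ref_chrom = chr, ref_start = ref_a, ref_end = ref_b,
          qry_contig = qry_name, qry_start = ref_a + qoff, qry_end = ref_b + qoff,
          orientation = "+", stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_ind)) {
      p <- ind_pos[k]; L <- ind_len[k]
      emit_block(prev, p)
      qry_chunks[[length(qry_chunks) + 1L]] <- bases[seq.int(prev + 1L, p)]
      if (ind_type[k] == "insertion") {       # present in BY, absent in RM
        polys[[length(polys) + 1L]] <- data.frame(
          kind = "insertion", chrom = chr, pos = p, ref_len = L, qry_len = 0L)
        prev <- p + L
        qoff <- qoff - L
      } else {                                 # absent in BY, present in RM
        polys[[length(polys) + 1L]] <- data.frame(
          kind = "deletion", chrom = chr, pos = p, ref_len = 0L, qry_len = L)
        qry_chunks[[length(qry_chunks) + 1L]] <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        prev <- p
        qoff <- qoff + L
      }
    }
    emit_block(prev, len)
    qry_chunks[[length(qry_chunks) + 1L]] <- bases[seq.int(prev + 1L, len)]
    qbases <- unlist(qry_chunks)

    # apply SNPs (substitute to a different base in the query)
    if (length(snp_pos)) {
      cb <- do.call(rbind, chr_blocks)
      bi <- findInterval(snp_pos, cb$ref_start)
      inside <- bi >= 1L & snp_pos < cb$ref_end[bi]
      snp_pos <- snp_pos[inside]; bi <- bi[inside]
      qpos <- snp_pos + (cb$qry_start[bi] - cb$ref_start[bi])
      for (s in seq_along(snp_pos)) {
        old <- bases[snp_pos[s] + 1L]
        qbases[qpos[s] + 1L] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      polys[[length(polys) + 1L]] <- data.frame(
        kind = "SNP", chrom = chr, pos = snp_pos, ref_len = 1L, qry_len = 1L)
    }
    by_seq[[chr]] <- paste(bases, collapse = "")
    rm_seq[[qry_name]] <- paste(qbases, collapse = "")
    blocks[[length(blocks) + 1L]] <- do.call(rbind, chr_blocks)
  }
  blocks <- do.call(rbind, blocks)
  polymorphisms <- do.call(rbind, polys)
  if (is.null(polymorphisms)) {
    polymorphisms <- data.frame(kind = character(), chrom = character(),
                                pos = integer(), ref_len = integer(),
                                qry_len = integer())
  }
  polymorphisms <- polymorphisms[order(polymorphisms$chrom, polymorphisms$pos), ]
  rownames(polymorphisms) <- NULL

  # feature annotations for enrichment analyses (rDNA-like + Ty-like)
  features <- list(
    rdna = data.frame(chrom = chroms[1], pos = floor(chr_len[1] * 0.6), side = "left"),
    ty = data.frame(chrom = sample(chroms, 3, replace = TRUE),
                    pos = sample(seq(30000, min(chr_len) - 30000), 3), side = "left"))
  list(by_seq = unlist(by_seq), rm_seq = unlist(rm_seq), blocks = blocks,
       polymorphisms = polymorphisms,
       chrom_lens = stats::setNames(chr_len, chroms), features = features)
}

# inverse of lift_intervals_to_ref: map reference intervals to the query
lift_intervals_to_qry <- function(ref_chrom, ref_start, ref_end, blocks) {
  n <- length(ref_start)
  out <- data.frame(qry_contig = rep(NA_character_, n),
                    qry_start = rep(NA_real_, n), qry_end = rep(NA_real_, n))
  if (n == 0L) return(out)
  iv <- GenomicRanges::GRanges(ref_chrom, IRanges::IRanges(ref_start + 1L, pmax(ref_end, ref_start + 1L)))
  bl <- GenomicRanges::GRanges(blocks$ref_chrom, IRanges::IRanges(blocks$ref_start + 1L, blocks$ref_end))
  hits <- GenomicRanges::findOverlaps(iv, bl, type = "within", select = "first")
  ok <- !is.na(hits)
  if (!any(ok)) return(out)
  b <- blocks[hits[ok], , drop = FALSE]
  rs <- ref_start[ok]; re <- ref_end[ok]
  plus <- b$orientation == "+"
  qs <- ifelse(plus, b$qry_start + (rs - b$ref_start), b$qry_start + (b$ref_end - re))
  out$qry_contig[ok] <- b$qry_contig
  out$qry_start[ok] <- qs
  out$qry_end[ok] <- qs + (re - rs)
  out
}

# gene models and a phased nucleosome landscape for one chromosome
layout_chromosome <- function(chr, len, cfg) {
  n_genes <- max(1L, round(len / 1000 * cfg$genes_per_kb))
  pitch <- floor(len / n_genes)
  cds_len <- min(1500L, pitch - 700L)
  genes <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    anchor <- (g - 1L) * pitch + 400L
    strand <- if (g %% 2L == 0L) "-" else "+"
    if (strand == "+") {
      cds_start <- anchor; cds_end <- anchor + cds_len
      tss <- cds_start - 60L; tes <- cds_end + 60L
    } else {
      cds_end <- anchor + cds_len; cds_start <- anchor
      tss <- cds_end + 60L; tes <- cds_start - 60L
    }
    data.frame(gene_id = sprintf("%s_g%03d", chr, g), chrom = chr, strand = strand,
               tss = tss, tes = tes, cds_start = cds_start, cds_end = cds_end,
               stringsAsFactors = FALSE)
  }))
  # NDR intervals upstream of each TSS
  ndr <- cbind(ifelse(genes$strand == "+", genes$tss - cfg$ndr_width_bp, genes$tss),
               ifelse(genes$strand == "+", genes$tss, genes$tss + cfg$ndr_width_bp))
  # phased nucleosome array over the chromosome, skipping NDRs
  starts <- integer(0); pos <- 10L
  while (pos + cfg$nucleosome_len_bp < len - 10L) {
    e <- pos + cfg$nucleosome_len_bp
    hit <- which(pos < ndr[, 2] & e > ndr[, 1])
    if (length(hit)) {
      pos <- as.integer(max(ndr[hit, 2]) + 2L)
      next
    }
    starts <- c(starts, pos)
    pos <- as.integer(e + sample(seq(cfg$linker_len_range[1], cfg$linker_len_range[2]), 1))
  }
  nucs <- data.frame(chrom = chr, start = starts,
                     end = starts + cfg$nucleosome_len_bp,
                     category = ifelse(stats::runif(length(starts)) < cfg$delocalized_frac,
                                       "delocalized", "well-positioned"),
                     stringsAsFactors = FALSE)
  list(genes = genes, nucs = nucs)
}

#' Simulate probe maps, intensity matrices, and the truth table
#'
#' Lays a gene-aware nucleosome landscape on the reference genome (NDR at
#' each TSS, phased nucleosomes elsewhere), mirrors it in query coordinates
#' through the edit script, tiles 25-mer probes, and draws replicate
#' intensities: nucleosome-mapping signal is Gaussian around the occupied
#' state's mean, ChIP signal adds a per-nucleosome acetylation offset
#' (shared between strains), and injected SNEPs shift that offset by
#' `log2(fold)` in one strain. Probes overlapping polymorphisms are emitted
#' (with a hybridization bias on the query-strain arrays) so that the probe
#' filtering stage is exercised; probes whose footprint cannot be lifted
#' into the query genome are absent from the query probe map.
#'
#' @param cfg a [sim_config()].
#' @param genomes output of [simulate_genomes()].
#' @return list `probes_by`, `probes_rm` (probe maps), `intensities`
#'   (log2-scale [intensity_matrix()], unnormalized), `truth` (list:
#'   `nuc_by`, `nuc_rm` (query coordinates), `sneps`, `genes`, `blocks`,
#'   `polymorphisms`, `features`).
#' @export
simulate_arrays <- function(cfg, genomes) {
  set.seed(cfg$seed + 1000L)
  blocks <- genomes$blocks
  chroms <- names(genomes$chrom_lens)

  all_genes <- list(); all_nucs <- list()
  for (chr in chroms) {
    lay <- layout_chromosome(chr, genomes$chrom_lens[[chr]], cfg)
    all_genes[[chr]] <- lay$genes
    all_nucs[[chr]] <- lay$nucs
  }
  genes <- do.call(rbind, all_genes); rownames(genes) <- NULL
  nuc_by <- do.call(rbind, all_nucs); rownames(nuc_by) <- NULL
  nuc_by$nuc_id <- seq_len(nrow(nuc_by))

  # mirror the landscape in query coordinates; nucleosomes hit by an indel
  # junction are dropped from the query strain
  lifted <- lift_intervals_to_qry(nuc_by$chrom, nuc_by$start, nuc_by$end, blocks)
  nuc_rm <- nuc_by
  nuc_rm$chrom <- lifted$qry_contig
  nuc_rm$start <- lifted$qry_start
  nuc_rm$end <- lifted$qry_end
  nuc_rm <- nuc_rm[!is.na(nuc_rm$start), , drop = FALSE]

  # SNEP injection among nucleosomes present in both strains
  eligible <- nuc_rm$nuc_id
  n_snep <- cfg$snep_count %||% round(0.09 * nrow(nuc_by))
  n_snep <- min(n_snep, length(eligible))
  snep_ids <- sort(sample(eligible, n_snep))
  snep_dir <- sample(c("BYac", "RMac"), n_snep, replace = TRUE,
                     prob = c(cfg$snep_byac_frac, 1 - cfg$snep_byac_frac))
  snep_fold <- stats::runif(n_snep, cfg$snep_fold_range[1], cfg$snep_fold_range[2])
  sneps <- data.frame(nuc_id = snep_ids, direction = snep_dir, fold = snep_fold,
                      chrom = nuc_by$chrom[snep_ids], start = nuc_by$start[snep_ids],
                      end = nuc_by$end[snep_ids], stringsAsFactors = FALSE)

  # per-nucleosome acetylation offsets (log2), shared then shifted by SNEPs
  ac <- cfg$ac_base + stats::rnorm(nrow(nuc_by), 0, cfg$ac_jitter)
  ac_by <- ac; ac_rm <- ac
  shift <- log2(snep_fold)
  ac_by[snep_ids] <- ac_by[snep_ids] + ifelse(snep_dir == "BYac", shift, 0)
  ac_rm[snep_ids] <- ac_rm[snep_ids] + ifelse(snep_dir == "RMac", shift, 0)

  # probe tiling on the reference
  probes_by <- do.call(rbind, lapply(chroms, function(chr) {
    s <- seq(0L, genomes$chrom_lens[[chr]] - cfg$probe_len, by = cfg$probe_spacing_bp)
    data.frame(probe_id = sprintf("%s_%07d", chr, s), chrom = chr, start = s,
               strand = "+", length = cfg$probe_len, n_matches = 1L,
               stringsAsFactors = FALSE)
  }))
  lift_p <- lift_intervals_to_qry(probes_by$chrom, probes_by$start,
                                  probes_by$start + cfg$probe_len, blocks)
  in_qry <- !is.na(lift_p$qry_start)
  probes_rm <- data.frame(probe_id = probes_by$probe_id[in_qry],
                          chrom = lift_p$qry_contig[in_qry],
                          start = lift_p$qry_start[in_qry], strand = "+",
                          length = cfg$probe_len, n_matches = 1L,
                          stringsAsFactors = FALSE)
  # a few ambiguous probes in the query genome, to exercise uniqueness filtering
  if (nrow(probes_rm) > 20L) {
    amb <- sample(nrow(probes_rm), 3L)
    probes_rm$n_matches[amb] <- 2L
  }

  # state and nucleosome assignment per probe, per strain
  assign_probe <- function(pmid, chrom, nucs) {
    idx <- rep(NA_integer_, length(pmid))
    for (chr in unique(chrom)) {
      i <- which(chrom == chr)
      nn <- nucs[nucs$chrom == chr, , drop = FALSE]
      if (nrow(nn) == 0L) next
      j <- findInterval(pmid[i], nn$start)
      hit <- j >= 1L & pmid[i] < nn$end[pmax(j, 1L)]
      idx[i][hit] <- nn$nuc_id[j[hit]]
    }
    idx
  }
  by_mid <- probes_by$start + cfg$probe_len / 2
  by_nuc_idx <- assign_probe(by_mid, probes_by$chrom, nuc_by)
  rm_mid <- probes_rm$start + cfg$probe_len / 2
  rm_nuc_idx <- assign_probe(rm_mid, probes_rm$chrom, nuc_rm)

  # categories are indexed by nuc_id (shared between strains)
  cat_lookup <- nuc_by$category
  state_mean <- function(idx) {
    m <- rep(cfg$mean_l, length(idx))
    in_n <- !is.na(idx)
    m[in_n] <- ifelse(cat_lookup[idx[in_n]] == "well-positioned", cfg$mean_w, cfg$mean_d)
    m
  }
  add_ac <- function(m, idx, ac_vec) {
    in_n <- !is.na(idx)
    m[in_n] <- m[in_n] + ac_vec[idx[in_n]]
    m
  }
  mean_nuc_by <- state_mean(by_nuc_idx)
  mean_chip_by <- add_ac(mean_nuc_by, by_nuc_idx, ac_by)

  # probes with a polymorphism in their reference footprint hybridize worse
  # on the query-strain arrays
  poly_iv <- polymorphism_intervals(genomes$polymorphisms)
  poly_hit <- rep(FALSE, nrow(probes_by))
  for (chr in chroms) {
    i <- which(probes_by$chrom == chr)
    j <- which(poly_iv$chrom == chr)
    poly_hit[i] <- overlaps_any(probes_by$start[i], probes_by$start[i] + cfg$probe_len,
                                poly_iv$start[j], poly_iv$end[j])
  }

  rm_row <- match(probes_by$probe_id, probes_rm$probe_id)
  has_rm <- !is.na(rm_row)
  idx_rm <- rm_nuc_idx[rm_row[has_rm]]
  mean_nuc_rm <- rep(cfg$mean_l - 1, nrow(probes_by))   # absent probes: background
  mean_chip_rm <- mean_nuc_rm
  mean_nuc_rm[has_rm] <- state_mean(idx_rm)
  mean_chip_rm[has_rm] <- add_ac(state_mean(idx_rm), idx_rm, ac_rm)
  mean_nuc_rm[poly_hit] <- mean_nuc_rm[poly_hit] + cfg$snp_bias
  mean_chip_rm[poly_hit] <- mean_chip_rm[poly_hit] + cfg$snp_bias

  # draw replicate arrays
  manifest <- rbind(
    expand.grid(strain = c("BY", "RM"), assay = "nuc",
                replicate = seq_len(cfg$n_nuc_replicates), stringsAsFactors = FALSE),
    expand.grid(strain = c("BY", "RM"), assay = "chip",
                replicate = seq_len(cfg$n_chip_replicates), stringsAsFactors = FALSE))
  manifest$array_id <- sprintf("%s_%s_%d", manifest$strain, manifest$assay, manifest$replicate)
  manifest <- manifest[, c("array_id", "strain", "assay", "replicate")]
  n_p <- nrow(probes_by)
  values <- matrix(NA_real_, n_p, nrow(manifest),
                   dimnames = list(probes_by$probe_id, manifest$array_id))
  for (a in seq_len(nrow(manifest))) {
    mu <- switch(paste(manifest$strain[a], manifest$assay[a]),
                 "BY nuc" = mean_nuc_by, "BY chip" = mean_chip_by,
                 "RM nuc" = mean_nuc_rm, "RM chip" = mean_chip_rm)
    v <- mu + stats::rnorm(n_p, 0, cfg$emission_sd)
    v[stats::runif(n_p) < cfg$missing_rate] <- NA_real_
    values[, a] <- v
  }

  list(probes_by = probes_by, probes_rm = probes_rm,
       intensities = intensity_matrix(values, manifest),
       truth = list(nuc_by = nuc_by, nuc_rm = nuc_rm, sneps = sneps,
                    genes = genes, blocks = blocks,
                    polymorphisms = genomes$polymorphisms,
                    features = genomes$features))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genomes()] then
#' [simulate_arrays()].
#'
#' @param cfg a [sim_config()].
#' @return the [simulate_arrays()] output with the genome list attached as
#'   `$genomes`.
#' @export
simulate_dataset <- function(cfg) {
  genomes <- simulate_genomes(cfg)
  out <- simulate_arrays(cfg, genomes)
  out$genomes <- genomes
  out
}

#' Write a simulated dataset to a directory
#'
#' Emits FASTA genomes (via Biostrings), TSV probe maps, intensities,
#' manifest, blocks and polymorphisms, a gene table, and BED truth tracks.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genomes$by_seq),
                              file.path(dir, "by_genome.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genomes$rm_seq),
                              file.path(dir, "rm_genome.fasta"))
  write_tsv(sim$probes_by, file.path(dir, "probes_by.tsv"))
  write_tsv(sim$probes_rm, file.path(dir, "probes_rm.tsv"))
  write_tsv(sim$truth$blocks, file.path(dir, "blocks.tsv"))
  write_tsv(sim$truth$polymorphisms, file.path(dir, "polymorphisms.tsv"))
  write_tsv(sim$truth$genes, file.path(dir, "genes.tsv"))
  write_tsv(sim$intensities$manifest, file.path(dir, "manifest.tsv"))
  vals <- data.frame(probe_id = rownames(sim$intensities$values),
                     sim$intensities$values, check.names = FALSE)
  write_tsv(vals, file.path(dir, "intensities.tsv"))
  truth_bed <- data.frame(chrom = sim$truth$nuc_by$chrom, start = sim$truth$nuc_by$start,
                          end = sim$truth$nuc_by$end,
                          name = paste0("nuc", sim$truth$nuc_by$nuc_id))
  utils::write.table(truth_bed, file.path(dir, "truth_nucleosomes_by.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  snep_bed <- data.frame(chrom = sim$truth$sneps$chrom, start = sim$truth$sneps$start,
                         end = sim$truth$sneps$end,
                         name = paste0(sim$truth$sneps$direction, "_",
                                       round(sim$truth$sneps$fold, 2)))
  utils::write.table(snep_bed, file.path(dir, "truth_sneps.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
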