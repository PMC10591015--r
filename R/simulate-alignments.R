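#' Describe a ChIP-seq-like pausing simulation
#'
#' Reads are placed in each gene's TSS region (TSSR) or gene-body region
#' (GBR) so that the expected per-bp read density ratio TSSR:GBR equals the
#' planted traveling ratio. A read lands in the TSSR with probability
#' `tr * L1 / (tr * L1 + L2)` and uniformly within the chosen region, so the
#' length-normalized region counts recover `tr` in expectation.
#'
#' @param gene_models GRanges from [generate_gene_models()].
#' @param true_tr planted traveling ratio, scalar or one value per gene (> 0).
#' @param depth total number of signal reads across all genes.
#' @param read_length read length in bp.
#' @param frac_low_mapq fraction of additional reads emitted with MAPQ < 30
#'   (placed uniformly on the chromosome; they must be filtered downstream).
#' @param tssr_length,gbr_length region lengths in bp (defaults 350 / 3000).
#' @param seed integer seed.
#' @return object of class `pausing_design`.
#' @export
pausing_design <- function(gene_models, true_tr = 2, depth = 1e5, read_length = 50,
                           frac_low_mapq = 0, tssr_length = 350, gbr_length = 3000,
                           seed = 1) {
  n <- length(gene_models)
  tr <- rep_len(true_tr, n)
  if (any(tr <= 0)) stopf("true TR must be > 0")
  if (any(GenomicRanges::width(gene_models) < tssr_length + gbr_length))
    stopf("gene bodies must be at least tssr_length + gbr_length bp")
  if (read_length > min(GenomicRanges::width(gene_models)))
    stopf("read_length exceeds the shortest gene")
  structure(list(gene_models = gene_models, true_tr = tr, depth = depth,
                 read_length = as.integer(read_length),
                 frac_low_mapq = frac_low_mapq,
                 tssr_length = as.integer(tssr_length),
                 gbr_length = as.integer(gbr_length),
                 seed = as.integer(seed)),
            class = "pausing_design")
}

#' Simulate single-end alignments with a planted traveling ratio
#'
#' @param design a [pausing_design()].
#' @return GRanges of alignments with `mapq` metadata; seqinfo inherited from
#'   the gene models. Deterministic for a fixed seed; draws use a per-gene
#'   counter so adding genes does not reshuffle existing ones.
#' @export
simulate_alignments <- function(design) {
  stopifnot(inherits(design, "pausing_design"))
  gm <- design$gene_models
  n <- length(gm)
  per_gene <- round(design$depth / n)
  L1 <- design$tssr_length; L2 <- design$gbr_length; rl <- design$read_length
  regions <- tr_regions(gm, L1, L2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- design$true_tr[i]
    p_tssr <- tr * L1 / (tr * L1 + L2)
    tssr <- regions$tssr[i]; gbr <- regions$gbr[i]
    draws <- with_seed(derive_seed(design$seed, i), {
      in_tssr <- runif(per_gene) < p_tssr
      # reads placed fully inside their region
      lo <- ifelse(in_tssr, GenomicRanges::start(tssr), GenomicRanges::start(gbr))
      hi <- ifelse(in_tssr, GenomicRanges::end(tssr), GenomicRanges::end(gbr)) - rl + 1L
      st <- as.integer(floor(runif(per_gene, lo, hi + 1)))
      rstrand <- sample(c("+", "-"), per_gene, replace = TRUE)
      n_low <- round(design$frac_low_mapq * per_gene)
      low <- NULL
      if (n_low > 0) {
        chlen <- GenomeInfoDb::seqlengths(gm)[as.character(GenomicRanges::seqnames(gm[i]))]
        low <- list(
          start = as.integer(floor(runif(n_low, 1, chlen - rl + 1))),
          mapq = sample(0:29, n_low, replace = TRUE),
          strand = sample(c("+", "-"), n_low, replace = TRUE)
        )
      }
      list(start = st, strand = rstrand, low = low)
    })
    chrom <- as.character(GenomicRanges::seqnames(gm[i]))
    starts <- draws$start; strands <- draws$strand
    mapqs <- rep(60L, length(starts))
    if (!is.null(draws$low)) {
      starts <- c(starts, draws$low$start)
      strands <- c(strands, draws$low$strand)
      mapqs <- c(mapqs, as.integer(draws$low$mapq))
    }
    out[[i]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = starts, width = rl),
      strand = strands, mapq = mapqs,
      seqinfo = GenomeInfoDb::seqinfo(gm)
    )
  }
  aln <- unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
  aln
}

#' Write alignments as a minimal single-end SAM file
#'
#' Emits a header (`@HD`, one `@SQ` per chromosome from the seqinfo) and one
#' record per alignment with FLAG 0/16 for strand, 1-based POS, the `mapq`
#' metadata column and a pure-match CIGAR.
#'
#' @param alignments GRanges with `mapq`.
#' @param path output `.sam` file.
#' @export
write_sam <- function(alignments, path) {
  sl <- GenomeInfoDb::seqlengths(alignments)
  if (any(is.na(sl))) stopf("alignments need seqlengths to write a SAM header")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl), con)
  n <- length(alignments)
  if (n > 0) {
    flag <- ifelse(as.character(GenomicRanges::strand(alignments)) == "-", 16L, 0L)
    rec <- sprintf("read%07d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                   seq_len(n), flag,
                   as.character(GenomicRanges::seqnames(alignments)),
                   GenomicRanges::start(alignments),
                   alignments$mapq,
                   GenomicRanges::width(alignments))
    writeLines(rec, con)
  }
  invisible(path)
}

#' Write alignments as BED6 (score column carries MAPQ)
#' @param alignments GRanges with `mapq`.
#' @param path output `.bed` file.
#' @export
write_alignment_bed <- function(alignments, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(alignments)),
    start = GenomicRanges::start(alignments) - 1L,
    end = GenomicRanges::end(alignments),
    name = sprintf("read%07d", seq_along(alignments)),
    score = alignments$mapq,
    strand = as.character(GenomicRanges::strand(alignments))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
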