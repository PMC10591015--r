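# Shared fixtures, built in code.

# One plus-strand gene on a small chromosome, with room for the default
# TSSR (350 bp) + GBR (3000 bp) windows and metagene flanks.
single_gene <- function(chrom_len = 20000L, start = 5001L, width = 6000L,
                        strand = "+") {
  gr <- GenomicRanges::GRanges("chrS1",
                               IRanges::IRanges(start = start, width = width),
                               strand = strand, gene_id = "geneA")
  GenomeInfoDb::seqlengths(gr) <- c(chrS1 = chrom_len)
  gr
}

# Alignments of fixed width at given 1-based starts, all MAPQ 60.
reads_at <- function(starts, width = 50L, chrom = "chrS1", chrom_len = 20000L,
                     mapq = 60L, strand = "+") {
  n <- length(starts)
  GenomicRanges::GRanges(rep_len(chrom, n),
                         IRanges::IRanges(start = starts, width = width),
                         strand = rep_len(strand, n),
                         mapq = rep_len(as.integer(mapq), n),
                         seqinfo = GenomeInfoDb::Seqinfo(chrom, as.integer(chrom_len)))
}

# Uniform coverage: 1-bp reads at every position, giving per-base pileup 1.
uniform_reads <- function(chrom_len = 20000L, chrom = "chrS1") {
  reads_at(seq_len(chrom_len), width = 1L, chrom = chrom, chrom_len = chrom_len)
}

# A tiny count matrix with two conditions.
toy_counts <- function(counts, conditions) {
  rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  count_matrix(counts, setNames(conditions, colnames(counts)))
}

# Independent reference: Benjamini-Hochberg step-up, spelled out.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
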