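#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene models on one or more synthetic chromosomes,
#' alternating strands so both orientations are represented. Gene lengths are
#' drawn uniformly between `min_length` and `2 * min_length` so that the
#' default traveling-ratio windows (350 bp TSS region + 3000 bp gene body)
#' always fit inside a gene.
#'
#' @param n_genes number of genes to place (>= 1).
#' @param chrom_length length of each synthetic chromosome in bp.
#' @param min_length minimum gene length in bp; default 3350 so the default
#'   TSSR+GBR windows fit.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param n_chroms number of synthetic chromosomes to spread genes over.
#' @return a [GenomicRanges::GRanges] with `gene_id` metadata and seqlengths
#'   set; strand is `+` or `-`.
#' @examples
#' gm <- generate_gene_models(5, 1e5, seed = 1)
#' @export
generate_gene_models <- function(n_genes, chrom_length, min_length = 3350, seed = 1,
                                 n_chroms = 1) {
  stopifnot(n_genes >= 1, min_length >= 1, n_chroms >= 1)
  gap <- 100L
  per_chrom <- ceiling(n_genes / n_chroms)
  # genes are placed on a fixed pitch; lengths go up to 2x min_length when
  # the chromosome has room, shrinking toward min_length when space is tight
  max_length <- min(2 * min_length, floor(chrom_length / per_chrom) - gap)
  if (max_length < min_length) {
    stopf("chrom_length %d too small to place %d genes of >= %d bp",
          chrom_length, n_genes, min_length)
  }
  pitch <- max_length + gap
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    chrom_idx <- ((i - 1L) %% n_chroms) + 1L
    slot <- (i - 1L) %/% n_chroms      # position index on its chromosome
    len <- with_seed(derive_seed(seed, i), {
      as.integer(floor(runif(1, min_length, max_length + 1)))
    })
    start0 <- slot * pitch             # 0-based slot origin
    strand <- if (with_seed(derive_seed(seed, i) + 1L, runif(1)) < 0.5) "+" else "-"
    # force both strands when >= 2 genes
    if (n_genes >= 2 && i <= 2) strand <- c("+", "-")[i]
    rows[[i]] <- data.frame(
      chrom = paste0("chrS", chrom_idx), start0 = start0, end0 = start0 + len,
      strand = strand, gene_id = sprintf("gene%04d", i),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    strand = df$strand,
    gene_id = df$gene_id
  )
  sl <- setNames(rep(as.integer(chrom_length), n_chroms),
                 paste0("chrS", seq_len(n_chroms)))
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Strand-aware TSS positions of gene models
#'
#' @param genes GRanges of gene models.
#' @return integer vector of 1-based TSS coordinates (5' end on the sense strand).
#' @export
gene_tss <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes), GenomicRanges::start(genes))
}

#' Strand-aware TES positions of gene models
#' @param genes GRanges of gene models.
#' @return integer vector of 1-based TES coordinates (3' end on the sense strand).
#' @export
gene_tes <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::start(genes), GenomicRanges::end(genes))
}

#' Write gene models as BED6
#'
#' BED is 0-based half-open; score column is 0.
#' @param genes GRanges with `gene_id`.
#' @param path output file.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    name = genes$gene_id,
    score = 0L,
    strand = as.character(GenomicRanges::strand(genes))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as a minimal GTF (gene features only)
#'
#' GTF is 1-based inclusive.
#' @param genes GRanges with `gene_id`.
#' @param path output file.
#' @export
write_gene_gtf <- function(genes, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes)),
    source = "pauseRescue",
    feature = "gene",
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    score = ".",
    strand = as.character(GenomicRanges::strand(genes)),
    frame = ".",
    attr = sprintf('gene_id "%s";', genes$gene_id)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED or GTF
#'
#' @param path a `.bed` (0-based half-open) or `.gtf`/`.gff` (1-based
#'   inclusive) annotation; format inferred from the extension.
#' @return GRanges with `gene_id` metadata.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    gr$gene_id <- gr$name
  } else if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene" | is.na(gr$type)]
  } else {
    stopf("unsupported gene model format: .%s", ext)
  }
  gr
}
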