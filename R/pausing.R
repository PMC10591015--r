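#' Configuration for traveling-ratio computation
#'
#' The TSS region (TSSR) covers the first `tssr_length` bp downstream of the
#' TSS on the sense strand; the gene-body region (GBR) is the `gbr_length` bp
#' immediately downstream of the TSSR. Alignments below `mapq_min` are
#' skipped, and genes whose length-normalized (and, when an input track is
#' supplied, input-normalized) TSSR signal falls below `min_tssr_signal` are
#' excluded as weak.
#'
#' @param tssr_length TSSR length in bp (default 350).
#' @param gbr_length GBR length in bp (default 3000).
#' @param mapq_min minimum MAPQ kept (inclusive; default 30).
#' @param min_tssr_signal weak-peak exclusion threshold on the TSSR signal
#'   (default 0.001).
#' @param count_mode `"overlap"` counts an alignment overlapping a region by
#'   >= 1 bp; `"five_prime"` requires the strand-aware 5' end in the region.
#' @return list of class `tr_config`.
#' @export
tr_config <- function(tssr_length = 350, gbr_length = 3000, mapq_min = 30,
                      min_tssr_signal = 0.001,
                      count_mode = c("overlap", "five_prime")) {
  stopifnot(tssr_length > 0, gbr_length > 0, min_tssr_signal >= 0)
  structure(list(tssr_length = as.integer(tssr_length),
                 gbr_length = as.integer(gbr_length),
                 mapq_min = mapq_min, min_tssr_signal = min_tssr_signal,
                 count_mode = match.arg(count_mode)),
            class = "tr_config")
}

#' Read alignments from SAM, BAM or BED
#'
#' SAM files are converted with samtools machinery (Rsamtools) and read as
#' genomic alignments; the MAPQ filter keeps records with `mapq >= mapq_min`.
#' BED input uses the score column as MAPQ; when absent the filter is
#' disabled with a warning.
#'
#' @param path `.sam`, `.bam` or `.bed` file.
#' @param mapq_min minimum MAPQ kept (inclusive).
#' @return GRanges with `mapq` metadata; the number of discarded records is
#'   reported via `message()` and stored in `attr(, "n_discarded")`.
#' @export
read_alignments <- function(path, mapq_min = 30) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$score) || all(is.na(gr$score))) {
      warning("BED input has no score column; MAPQ filter disabled")
      gr$mapq <- NA_integer_
      attr(gr, "n_discarded") <- 0L
      return(gr)
    }
    gr$mapq <- as.integer(gr$score)
    gr$score <- NULL
  } else if (ext %in% c("sam", "bam")) {
    bam <- path
    if (ext == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    }
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(what = "mapq"))
    gr <- GenomicRanges::granges(ga)
    gr$mapq <- S4Vectors::mcols(ga)$mapq
  } else {
    stopf("unsupported alignment format: .%s", ext)
  }
  keep <- !is.na(gr$mapq) & gr$mapq >= mapq_min
  n_disc <- sum(!keep)
  out <- gr[keep]
  message(sprintf("read_alignments: kept %d records, discarded %d below MAPQ %d",
                  length(out), n_disc, mapq_min))
  attr(out, "n_discarded") <- n_disc
  out
}

#' Binned, normalized coverage track
#'
#' For 1-bp bins the track is the per-base pileup; for wider bins each bin's
#' value is the number of reads overlapping it. Under RPKM normalization each
#' value is scaled by `1e9 / (bin_width * total_mapped_reads)`.
#'
#' @param alignments GRanges of reads (already MAPQ-filtered).
#' @param bin bin width in bp (default 1).
#' @param normalization `"rpkm"` or `"raw"`.
#' @return list of class `coverage_track`: `cov` (an [IRanges::RleList] of
#'   per-bin values, one Rle per chromosome), `bin`, `normalization`,
#'   `total_reads`, `scale`.
#' @export
coverage_track <- function(alignments, bin = 1, normalization = c("rpkm", "raw")) {
  normalization <- match.arg(normalization)
  total <- length(alignments)
  if (normalization == "rpkm" && total == 0)
    stopf("RPKM normalization needs at least one mapped read")
  scale <- if (normalization == "rpkm") 1e9 / (bin * total) else 1
  if (bin == 1) {
    cov <- GenomicRanges::coverage(alignments)
  } else {
    sl <- GenomeInfoDb::seqlengths(alignments)
    if (any(is.na(sl))) stopf("binned coverage needs seqlengths")
    tiles <- GenomicRanges::tileGenome(sl, tilewidth = bin, cut.last.tile.in.chrom = TRUE)
    hits <- GenomicRanges::countOverlaps(tiles, alignments, ignore.strand = TRUE)
    cov <- GenomicRanges::coverage(tiles, weight = hits)   # per-bp expansion of bin counts
  }
  structure(list(cov = cov * scale, bin = bin, normalization = normalization,
                 total_reads = total, scale = scale),
            class = "coverage_track")
}

#' Export a coverage track as bedGraph (0-based half-open)
#' @param track a [coverage_track()].
#' @param path output `.bedGraph` file.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$cov)
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Count alignments overlapping a region
#'
#' @param alignments GRanges of reads.
#' @param region GRanges of one or more regions.
#' @param length_normalize divide each count by its region length.
#' @param mode `"overlap"` (>= 1 bp overlap) or `"five_prime"` (strand-aware
#'   5' end inside the region).
#' @return numeric vector of signals, one per region.
#' @export
count_region <- function(alignments, region, length_normalize = FALSE,
                         mode = c("overlap", "five_prime")) {
  mode <- match.arg(mode)
  reads <- if (mode == "five_prime") {
    GenomicRanges::resize(alignments, width = 1, fix = "start")
  } else alignments
  n <- GenomicRanges::countOverlaps(region, reads, ignore.strand = TRUE)
  if (length_normalize) n / GenomicRanges::width(region) else as.numeric(n)
}

# Strand-aware TSSR/GBR windows for each gene: TSSR = [TSS, TSS + L1) on the
# sense strand, GBR = [TSS + L1, TSS + L1 + L2).
tr_regions <- function(genes, L1, L2) {
  tss <- gene_tss(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  chr <- as.character(GenomicRanges::seqnames(genes))
  tssr <- GenomicRanges::GRanges(chr, IRanges::IRanges(
    start = ifelse(minus, tss - L1 + 1L, tss),
    end   = ifelse(minus, tss, tss + L1 - 1L)))
  gbr <- GenomicRanges::GRanges(chr, IRanges::IRanges(
    start = ifelse(minus, tss - L1 - L2 + 1L, tss + L1),
    end   = ifelse(minus, tss - L1, tss + L1 + L2 - 1L)))
  list(tssr = tssr, gbr = gbr)
}

#' Traveling ratio per gene
#'
#' TR = (reads in TSSR / L1) / (reads in GBR / L2). Genes shorter than
#' L1 + L2 get status `too_short`; genes whose TSSR signal falls below
#' `min_tssr_signal` get status `filtered_weak` and no TR. When `input`
#' alignments are supplied, each region signal is divided by the
#' corresponding input signal (length-normalized, pseudocount 1e-9).
#'
#' @param genes GRanges of gene models with `gene_id`.
#' @param alignments GRanges of MAPQ-filtered reads.
#' @param config a [tr_config()].
#' @param input optional GRanges of input (control) reads.
#' @return data.frame of class `tr_table`: `gene, tssr_signal, gbr_signal,
#'   tr, status`.
#' @export
traveling_ratio <- function(genes, alignments, config = tr_config(), input = NULL) {
  L1 <- config$tssr_length; L2 <- config$gbr_length
  reg <- tr_regions(genes, L1, L2)
  tssr_sig <- count_region(alignments, reg$tssr, length_normalize = TRUE,
                           mode = config$count_mode)
  gbr_sig <- count_region(alignments, reg$gbr, length_normalize = TRUE,
                          mode = config$count_mode)
  if (!is.null(input)) {
    in_t <- count_region(input, reg$tssr, length_normalize = TRUE, mode = config$count_mode)
    in_g <- count_region(input, reg$gbr, length_normalize = TRUE, mode = config$count_mode)
    tssr_sig <- tssr_sig / (in_t + 1e-9)
    gbr_sig <- gbr_sig / (in_g + 1e-9)
  }
  too_short <- GenomicRanges::width(genes) < L1 + L2
  weak <- !too_short & tssr_sig < config$min_tssr_signal
  status <- ifelse(too_short, "too_short", ifelse(weak, "filtered_weak", "ok"))
  tr <- ifelse(status == "ok", tssr_sig / gbr_sig, NA_real_)
  out <- data.frame(gene = genes$gene_id, tssr_signal = tssr_sig,
                    gbr_signal = gbr_sig, tr = tr, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("tr_table", "data.frame")
  out
}

#' Configuration for metagene profiles
#'
#' @param upstream bp upstream of the TSS kept at native resolution
#'   (default 1000).
#' @param downstream_of_tes bp downstream of the TES kept at native
#'   resolution (default 1500).
#' @param body_target bp the gene body is rescaled to (default 3000).
#' @param bin bin size in bp (default 1).
#' @return list of class `metagene_config`.
#' @export
metagene_config <- function(upstream = 1000, downstream_of_tes = 1500,
                            body_target = 3000, bin = 1) {
  stopifnot(upstream > 0, downstream_of_tes > 0, body_target > 0, bin > 0)
  structure(list(upstream = as.integer(upstream),
                 downstream_of_tes = as.integer(downstream_of_tes),
                 body_target = as.integer(body_target), bin = as.integer(bin)),
            class = "metagene_config")
}

# per-base numeric coverage for [from, to] on one chromosome, zero-padded
# outside chromosome bounds
cov_window <- function(cov, chrom, from, to) {
  r <- cov[[chrom]]
  n <- length(r)
  lo <- max(1L, from); hi <- min(n, to)
  v <- numeric(to - from + 1L)
  if (lo <= hi) v[(lo - from + 1L):(hi - from + 1L)] <- as.numeric(r[lo:hi])
  v
}

#' Averaged metagene coverage profile
#'
#' Per gene, the RPKM coverage over the 1 kb upstream of the TSS and the
#' 1.5 kb downstream of the TES is kept at per-base resolution while the gene
#' body is rescaled to `body_target` bins by linear interpolation;
#' minus-strand genes are reversed so every profile reads 5' to 3'. The
#' returned vector is the mean across genes and has length
#' `upstream + body_target + downstream_of_tes`.
#'
#' @param alignments GRanges of MAPQ-filtered reads, or a [coverage_track()].
#' @param genes GRanges of gene models.
#' @param config a [metagene_config()].
#' @return numeric profile vector with attribute `n_genes` (genes used).
#' @export
metagene_profile <- function(alignments, genes, config = metagene_config()) {
  if (length(genes) == 0) stopf("no genes supplied")
  track <- if (inherits(alignments, "coverage_track")) alignments
           else coverage_track(alignments, bin = config$bin)
  cov <- track$cov
  up <- config$upstream; dn <- config$downstream_of_tes; bt <- config$body_target
  acc <- numeric(up + bt + dn)
  used <- 0L
  for (i in seq_along(genes)) {
    w <- GenomicRanges::width(genes[i])
    if (w < 2) { message(sprintf("metagene: skipping %s (body < 2 bins)", genes$gene_id[i])); next }
    chrom <- as.character(GenomicRanges::seqnames(genes[i]))
    minus <- as.character(GenomicRanges::strand(genes[i])) == "-"
    s <- GenomicRanges::start(genes[i]); e <- GenomicRanges::end(genes[i])
    v <- if (minus) rev(cov_window(cov, chrom, s - dn, e + up))
         else cov_window(cov, chrom, s - up, e + dn)
    upstream_v <- v[seq_len(up)]
    body_v <- v[(up + 1):(up + w)]
    down_v <- v[(up + w + 1):(up + w + dn)]
    body_scaled <- approx(seq_len(w), body_v, xout = seq(1, w, length.out = bt))$y
    acc <- acc + c(upstream_v, body_scaled, down_v)
    used <- used + 1L
  }
  if (used == 0) stopf("all genes skipped")
  prof <- acc / used
  attr(prof, "n_genes") <- used
  prof
}

#' Per-gene RPKM signal in a fixed window around the TSS
#'
#' The window `[tss + offset_start, tss + offset_end)` is taken along the
#' sense strand (offsets are flipped for minus-strand genes). The signal is
#' reads overlapping the window times `1e9 / (width * total mapped reads)`.
#'
#' @param alignments GRanges of MAPQ-filtered reads.
#' @param genes GRanges of gene models with `gene_id`.
#' @param window numeric `c(offset_start, offset_end)` relative to the TSS
#'   (e.g. `c(-500, 500)` for the TSS window, `c(500, 2500)` for gene body).
#' @return data.frame `gene, signal` (RPKM units).
#' @export
window_signal <- function(alignments, genes, window = c(-500, 500)) {
  if (window[2] <= window[1]) stopf("window must have positive width")
  tss <- gene_tss(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  a <- as.integer(window[1]); b <- as.integer(window[2])
  reg <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes)),
    IRanges::IRanges(start = ifelse(minus, tss - b + 1L, tss + a),
                     end   = ifelse(minus, tss - a, tss + b - 1L)))
  total <- length(alignments)
  if (total == 0) stopf("RPKM needs at least one mapped read")
  n <- count_region(alignments, reg)
  data.frame(gene = genes$gene_id,
             signal = n * 1e9 / (GenomicRanges::width(reg) * total),
             stringsAsFactors = FALSE)
}
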