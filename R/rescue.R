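#' Classify knockout-dependent genes
#'
#' A gene is dependent on the depleted factor iff it is significantly changed
#' in the knockout contrast (knockout vs unperturbed reference) AND
#' significantly changed in the WT-rescue contrast (WT construct vs knockout)
#' in the opposite direction — i.e. restored by re-expression.
#'
#' @param ko_contrast `contrast_result` of knockout vs reference.
#' @param rescue_contrast `contrast_result` of WT construct vs knockout.
#' @param thresholds a [de_thresholds()].
#' @param use_shrunk compare shrunken LFCs against the threshold.
#' @return character vector of dependent gene ids.
#' @export
classify_dependent_genes <- function(ko_contrast, rescue_contrast,
                                     thresholds = de_thresholds(),
                                     use_shrunk = TRUE) {
  if (!identical(ko_contrast$gene, rescue_contrast$gene))
    stopf("contrasts cover different gene universes")
  ko <- call_de(ko_contrast, thresholds, use_shrunk)
  rs <- call_de(rescue_contrast, thresholds, use_shrunk)
  dep <- ko$called & rs$called & ko$direction != rs$direction
  ko$gene[dep]
}

#' Compute the gene rescue capability (GRC)
#'
#' For each dependent gene, GRC = (LFC_MT - LFC_KO) / (LFC_WT - LFC_KO),
#' where all three log2 fold changes are taken against the same unperturbed
#' reference condition. By construction the knockout anchors at 0 (no rescue)
#' and the WT construct at 1 (full rescue). Genes whose denominator is
#' smaller than `denominator_epsilon` in absolute value are excluded with
#' reason `small_denominator`; raw GRC values are reported unclipped.
#'
#' @param lfc_ko,lfc_wt,lfc_mt named numeric vectors of log2 fold changes vs
#'   the common reference for the knockout, the WT construct and the mutant
#'   construct; names are gene ids.
#' @param genes gene ids to compute over (typically the dependent set).
#' @param denominator_epsilon exclusion threshold in log2 units.
#' @return data.frame of class `grc_table` with columns `gene, lfc_ko,
#'   lfc_wt, lfc_mt, grc, excluded_reason`.
#' @export
compute_grc <- function(lfc_ko, lfc_wt, lfc_mt, genes = names(lfc_ko),
                        denominator_epsilon = 1e-6) {
  need <- function(v, nm) {
    if (!all(genes %in% names(v))) stopf("missing %s LFCs for some genes", nm)
    v[genes]
  }
  ko <- need(lfc_ko, "knockout"); wt <- need(lfc_wt, "WT"); mt <- need(lfc_mt, "mutant")
  if (!all(is.finite(c(ko, wt, mt)))) stopf("LFC values must be finite")
  denom <- wt - ko
  small <- abs(denom) < denominator_epsilon
  grc <- ifelse(small, NA_real_, (mt - ko) / denom)
  out <- data.frame(
    gene = genes, lfc_ko = unname(ko), lfc_wt = unname(wt), lfc_mt = unname(mt),
    grc = unname(grc),
    excluded_reason = ifelse(small, "small_denominator", "none"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("grc_table", "data.frame")
  out
}

#' Restoration distribution and fraction restored over 50%
#'
#' Bins non-excluded GRC values into `n_bins` equal-width bins over [0, 1];
#' values below 0 or above 1 (under-/over-rescue) accumulate in the edge
#' bins. The fraction restored over half uses raw (unclipped) values.
#'
#' @param table a `grc_table` from [compute_grc()].
#' @param n_bins number of histogram bins over [0, 1].
#' @return list with `histogram` (data.frame `bin_lo, bin_hi, count`),
#'   `fraction_over_half`, `n` (non-excluded genes), `n_excluded`.
#' @export
restoration_distribution <- function(table, n_bins = 20) {
  stopifnot(n_bins >= 1)
  g <- table$grc[table$excluded_reason == "none"]
  n_excl <- sum(table$excluded_reason != "none")
  if (length(g) == 0) {
    return(list(histogram = data.frame(bin_lo = numeric(), bin_hi = numeric(),
                                       count = integer()),
                fraction_over_half = NA_real_, n = 0L, n_excluded = n_excl))
  }
  edges <- seq(0, 1, length.out = n_bins + 1)
  clamped <- pmin(pmax(g, 0), 1)
  idx <- pmin(pmax(findInterval(clamped, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(
    histogram = data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                           count = counts),
    fraction_over_half = mean(g > 0.5),
    n = length(g), n_excluded = n_excl
  )
}

#' Stratify GRC by factor binding at promoters
#'
#' Splits the non-excluded dependent genes into bound and unbound strata and
#' compares their restoration, reporting the difference in medians and a
#' Wilcoxon rank-sum p-value.
#'
#' @param table a `grc_table`.
#' @param bound_genes character vector of bound gene ids (e.g. genes with a
#'   ChIP peak overlapping the TSS window).
#' @param n_bins bins for each stratum's distribution.
#' @return list with `bound`, `unbound` (each a [restoration_distribution()]
#'   result plus its `grc_table`), `median_difference` (bound - unbound) and
#'   `p_ranksum`; empty strata are flagged with `NA` summaries.
#' @export
stratify_by_binding <- function(table, bound_genes, n_bins = 20) {
  ok <- table[table$excluded_reason == "none", , drop = FALSE]
  is_bound <- ok$gene %in% bound_genes
  tb <- ok[is_bound, , drop = FALSE]; tu <- ok[!is_bound, , drop = FALSE]
  summ <- function(t) c(list(table = t), restoration_distribution(t, n_bins))
  med_diff <- if (nrow(tb) && nrow(tu)) median(tb$grc) - median(tu$grc) else NA_real_
  p <- if (nrow(tb) && nrow(tu)) wilcox.test(tb$grc, tu$grc)$p.value else NA_real_
  list(bound = summ(tb), unbound = summ(tu),
       median_difference = med_diff, p_ranksum = p)
}

#' Read a bound-gene set
#'
#' Either a plain text file with one gene id per line, or a BED file of peaks
#' combined with gene models: a gene is "bound" when a peak overlaps its TSS
#' +/- `window` bp.
#'
#' @param path gene list (.txt) or peak BED (.bed).
#' @param genes GRanges of gene models, required for peak input.
#' @param window half-width of the promoter window around the TSS in bp.
#' @return character vector of bound gene ids.
#' @export
read_bound_genes <- function(path, genes = NULL, window = 1000) {
  if (tolower(tools::file_ext(path)) == "bed") {
    if (is.null(genes)) stopf("gene models required to interpret a peak BED")
    peaks <- rtracklayer::import(path, format = "BED")
    tss <- gene_tss(genes)
    prom <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(genes),
      IRanges::IRanges(pmax(1L, tss - as.integer(window)), tss + as.integer(window))
    )
    hits <- GenomicRanges::countOverlaps(prom, peaks, ignore.strand = TRUE) > 0
    genes$gene_id[hits]
  } else {
    readLines(path)
  }
}

#' Write a GRC table and its histogram as TSV
#' @param table a `grc_table`.
#' @param dist a [restoration_distribution()] result.
#' @param table_path,hist_path output files.
#' @export
write_grc_tsv <- function(table, dist, table_path, hist_path) {
  write_tsv_det(as.data.frame(table), table_path)
  write_tsv_det(dist$histogram, hist_path)
  invisible(c(table_path, hist_path))
}
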