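#' Simulate a cell-line expression panel with planted correlations
#'
#' The target gene is standard normal across cell lines; each other gene g
#' with planted correlation r is generated as
#' `r * z_target + sqrt(1 - r^2) * eps + noise`, so the sample Pearson
#' correlation converges to r as the panel grows.
#'
#' @param n_cell_lines number of cell lines (>= 3).
#' @param target_gene id of the target gene.
#' @param planted_r named numeric vector, gene id -> correlation in [-1, 1].
#' @param noise_sd additional independent noise added to every non-target
#'   gene (attenuates the planted correlation; default 0).
#' @param seed integer seed.
#' @return numeric matrix, rows = cell lines, columns = genes (DepMap
#'   export layout).
#' @export
simulate_expression_panel <- function(n_cell_lines, target_gene, planted_r,
                                      noise_sd = 0, seed = 1) {
  if (n_cell_lines < 3) stopf("need at least 3 cell lines")
  if (any(abs(planted_r) > 1)) stopf("planted correlations must be in [-1, 1]")
  z <- with_seed(derive_seed(seed, 0), rnorm(n_cell_lines))
  m <- matrix(NA_real_, nrow = n_cell_lines, ncol = length(planted_r) + 1,
              dimnames = list(sprintf("CL%04d", seq_len(n_cell_lines)),
                              c(target_gene, names(planted_r))))
  m[, target_gene] <- z
  for (i in seq_along(planted_r)) {
    r <- planted_r[i]
    eps <- with_seed(derive_seed(seed, i), rnorm(n_cell_lines))
    g <- r * z + sqrt(1 - r^2) * eps
    if (noise_sd > 0)
      g <- g + with_seed(derive_seed(seed, i) + 7L, rnorm(n_cell_lines, 0, noise_sd))
    m[, names(planted_r)[i]] <- g
  }
  m
}

#' Rank genome-wide Pearson coexpression against a target gene
#'
#' @param mat numeric matrix, rows = cell lines, columns = genes.
#' @param target target gene id (must be a column); excluded from its own
#'   ranking.
#' @param min_complete minimum fraction of complete pairs vs the target for a
#'   gene to be ranked (others are dropped with a message).
#' @return data.frame `gene, r` sorted by descending r, ties broken
#'   lexicographically by gene id; zero-variance genes are flagged in
#'   `attr(, "flagged")` and excluded.
#' @export
correlate <- function(mat, target, min_complete = 0.5) {
  if (!target %in% colnames(mat)) stopf("target %s not in matrix", target)
  if (nrow(mat) < 3) stopf("need at least 3 cell lines")
  tz <- mat[, target]
  if (sd(tz, na.rm = TRUE) == 0 || is.na(sd(tz, na.rm = TRUE)))
    stopf("target gene has zero variance")
  others <- setdiff(colnames(mat), target)
  complete_frac <- colMeans(!is.na(mat[, others, drop = FALSE]) & !is.na(tz))
  keep <- complete_frac >= min_complete
  if (any(!keep))
    message(sprintf("correlate: dropping %d genes with < %.0f%% complete pairs",
                    sum(!keep), 100 * min_complete))
  others <- others[keep]
  r <- suppressWarnings(
    as.numeric(cor(tz, mat[, others, drop = FALSE], use = "pairwise.complete.obs")))
  flagged <- others[is.na(r)]   # zero variance or no complete pairs
  ok <- !is.na(r)
  df <- data.frame(gene = others[ok], r = r[ok], stringsAsFactors = FALSE)
  df <- df[order(-df$r, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "flagged") <- flagged
  df
}

#' Top-N positively ranked coexpressed genes
#'
#' @param ranked data.frame from [correlate()] (descending r).
#' @param n number of genes to keep (default 1000).
#' @param by_abs rank by |r| instead of signed r.
#' @return character vector of gene ids, length `min(n, nrow(ranked))`.
#' @export
top_n_genes <- function(ranked, n = 1000, by_abs = FALSE) {
  if (n <= 0) stopf("n must be positive")
  if (by_abs) {
    ranked <- ranked[order(-abs(ranked$r), ranked$gene), , drop = FALSE]
  }
  head(ranked$gene, n)
}

#' Multi-set intersection (UpSet) region counts and unique sets
#'
#' Computes the mutually disjoint membership regions over >= 2 gene sets
#' (every nonempty combination), plus for each set the genes belonging to it
#' and no other.
#'
#' @param sets named list of character vectors.
#' @return list with `regions` (data.frame `combination` —
#'   `+`-joined set names — and `count`, only nonempty regions) and
#'   `unique_sets` (named list of genes unique to each set).
#' @export
set_overlaps <- function(sets) {
  if (length(sets) < 2) stopf("need at least 2 sets")
  if (is.null(names(sets))) stopf("sets must be named")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "+"))
  tab <- table(key)
  regions <- data.frame(combination = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  regions <- regions[order(-regions$count, regions$combination), , drop = FALSE]
  rownames(regions) <- NULL
  uniq <- lapply(names(sets), function(nm) {
    universe[member[, nm] & rowSums(member) == 1]
  })
  names(uniq) <- names(sets)
  list(regions = regions, unique_sets = uniq)
}

#' Read a cell-line expression matrix from CSV/TSV
#'
#' DepMap export layout (rows = cell lines, columns = genes) is assumed; a
#' transposed layout is auto-detected when there are many more rows than
#' columns and `layout = "auto"`.
#'
#' @param path `.csv` or `.tsv`/`.txt` file; first column holds row ids.
#' @param layout `"auto"`, `"lines_by_genes"` or `"genes_by_lines"`.
#' @return numeric matrix, rows = cell lines, columns = genes.
#' @export
read_expression_matrix <- function(path, layout = c("auto", "lines_by_genes", "genes_by_lines")) {
  layout <- match.arg(layout)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (layout == "genes_by_lines" || (layout == "auto" && nrow(m) > 5 * ncol(m))) {
    m <- t(m)
  }
  m
}
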