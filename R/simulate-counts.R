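#' Describe a knockout-plus-rescue RNA-seq design
#'
#' Encodes the six-condition rescue layout used throughout the package: an
#' unperturbed reference (empty vector, no Cre), the knockout (empty vector +
#' Cre), and re-expression constructs in the knockout background, each with a
#' true per-gene restoration fraction `r` in [0, 1]. A dependent gene carries
#' a planted knockout effect `delta` (log2); under a construct with rescue
#' fraction `r` its planted log2 fold change versus the reference is
#' `(1 - r) * delta`, which makes the true gene rescue capability of that
#' construct equal `r` by construction.
#'
#' @param n_genes number of genes.
#' @param frac_dependent fraction of genes carrying a knockout effect.
#' @param ko_lfc_location,ko_lfc_scale location and scale of the magnitude of
#'   planted knockout log2 effects; each dependent gene gets
#'   `sign * Normal(location, scale)` with a random sign (magnitudes
#'   truncated below at 0.75 so planted effects stay detectable).
#' @param rescue_fractions named numeric vector of construct restoration
#'   fractions; the WT construct must map to 1. The reference and knockout
#'   conditions are implicit (fractions 0).
#' @param dispersion NB dispersion alpha >= 0 (variance = mu + alpha mu^2).
#' @param baseline_log_mean,baseline_log_sd lognormal parameters of per-gene
#'   baseline expression means.
#' @param library_sizes optional per-sample scale factors (recycled across
#'   samples in column order); default all 1.
#' @param replicates replicates per condition (>= 2).
#' @param seed integer seed.
#' @return an object of class `rescue_design`.
#' @export
rescue_design <- function(n_genes = 2000,
                          frac_dependent = 0.3,
                          ko_lfc_location = 2,
                          ko_lfc_scale = 0.5,
                          rescue_fractions = c(WT = 1, MT194 = 0.7, MT486 = 0.8),
                          dispersion = 0.05,
                          baseline_log_mean = log(500),
                          baseline_log_sd = 1,
                          library_sizes = NULL,
                          replicates = 2,
                          seed = 1) {
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (replicates < 2) stopf("replicates must be >= 2")
  if (!all(is.finite(rescue_fractions))) stopf("rescue fractions must be finite")
  if (is.null(names(rescue_fractions)) || any(names(rescue_fractions) == ""))
    stopf("rescue_fractions must be a named vector")
  if (!is.null(library_sizes) && any(library_sizes <= 0))
    stopf("library sizes must be positive")
  conditions <- c("EV", "KO", names(rescue_fractions))
  structure(list(
    n_genes = as.integer(n_genes), frac_dependent = frac_dependent,
    ko_lfc_location = ko_lfc_location, ko_lfc_scale = ko_lfc_scale,
    rescue_fractions = rescue_fractions, dispersion = dispersion,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    library_sizes = library_sizes, replicates = as.integer(replicates),
    conditions = conditions, seed = as.integer(seed)
  ), class = "rescue_design")
}

#' Simulate an RNA-seq count matrix for a rescue design
#'
#' Counts are negative binomial with mean
#' `mu[gene, cond] = baseline * 2^(planted LFC) * library_size` and variance
#' `mu + alpha * mu^2`. Draws are expanded from the design seed with a
#' per-gene counter so enlarging `n_genes` never reshuffles existing genes.
#'
#' @param design a [rescue_design()].
#' @return list with `counts` (a [count_matrix()]) and `truth` (data.frame of
#'   per-gene baseline, dependence flag, planted knockout effect `delta`, and
#'   one `lfc_<construct>` column per condition giving the planted log2 fold
#'   change versus the reference).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "rescue_design"))
  conds <- design$conditions
  nrep <- design$replicates
  sample_cond <- rep(conds, each = nrep)
  sample_ids <- paste0(sample_cond, "_rep", rep(seq_len(nrep), times = length(conds)))
  ns <- length(sample_ids)
  libs <- if (is.null(design$library_sizes)) rep(1, ns) else rep_len(design$library_sizes, ns)

  counts <- matrix(0L, nrow = design$n_genes, ncol = ns)
  truth <- data.frame(
    gene = sprintf("gene%05d", seq_len(design$n_genes)),
    baseline = NA_real_, dependent = FALSE, delta = 0,
    stringsAsFactors = FALSE
  )
  # planted LFC vs reference per condition
  cond_lfc_factor <- c(EV = 0, KO = 1, 1 - design$rescue_fractions)
  names(cond_lfc_factor) <- conds

  for (i in seq_len(design$n_genes)) {
    row <- with_seed(derive_seed(design$seed, i), {
      baseline <- rlnorm(1, design$baseline_log_mean, design$baseline_log_sd)
      dependent <- runif(1) < design$frac_dependent   # per-gene stream: stable under n_genes changes
      delta <- 0
      if (dependent) {
        mag <- max(0.75, rnorm(1, design$ko_lfc_location, design$ko_lfc_scale))
        delta <- mag * sample(c(-1, 1), 1)
      }
      mu <- baseline * 2^(cond_lfc_factor[sample_cond] * delta) * libs
      k <- if (design$dispersion == 0) rpois(ns, mu)
           else rnbinom(ns, mu = mu, size = 1 / design$dispersion)
      list(baseline = baseline, dependent = dependent, delta = delta, k = k)
    })
    counts[i, ] <- as.integer(row$k)
    truth$baseline[i] <- row$baseline
    truth$dependent[i] <- row$dependent
    truth$delta[i] <- row$delta
  }
  for (cc in conds) truth[[paste0("lfc_", cc)]] <- cond_lfc_factor[[cc]] * truth$delta
  for (cc in names(design$rescue_fractions))
    truth[[paste0("r_", cc)]] <- design$rescue_fractions[[cc]]

  rownames(counts) <- truth$gene
  colnames(counts) <- sample_ids
  cm <- count_matrix(counts, setNames(sample_cond, sample_ids))
  list(counts = cm, truth = truth)
}

#' Write a count matrix and its sample sheet as TSV
#'
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path output files. The counts TSV has a `gene`
#'   id column followed by one column per sample; the sample sheet has
#'   `sample` and `condition` columns.
#' @export
write_counts_tsv <- function(cm, counts_path, samples_path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts, check.names = FALSE)
  write_tsv_det(df, counts_path)
  write_tsv_det(data.frame(sample = colnames(cm$counts),
                           condition = unname(cm$conditions[colnames(cm$counts)])),
                samples_path)
  invisible(c(counts_path, samples_path))
}

#' Read a count matrix and sample sheet written by [write_counts_tsv()]
#' @param counts_path,samples_path input files.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  df <- read_tsv_det(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  ss <- read_tsv_det(samples_path)
  count_matrix(m, setNames(ss$condition, ss$sample))
}
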