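#' Construct a count matrix with sample-to-condition mapping
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param conditions named character vector mapping every sample id to a
#'   condition label.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, conditions) {
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("counts must have unique gene ids as rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stopf("counts must have unique sample ids as colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  missing <- setdiff(colnames(counts), names(conditions))
  if (length(missing)) stopf("samples without a condition: %s", paste(missing, collapse = ", "))
  structure(list(counts = counts, conditions = conditions[colnames(counts)]),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (expressed in
#' every sample) of the ratio of that sample's count to the gene's geometric
#' mean across samples. This makes libraries comparable without being driven
#' by a handful of highly expressed genes.
#'
#' @param cm a [count_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  k <- cm$counts
  allnz <- rowSums(k == 0) == 0
  if (!any(allnz)) stopf("no gene expressed in all samples; cannot normalize")
  ref <- exp(rowMeans(log(k[allnz, , drop = FALSE])))
  sf <- apply(k[allnz, , drop = FALSE], 2, function(x) median(x / ref))
  if (any(!is.finite(sf)) || any(sf <= 0)) stopf("degenerate size factors")
  sf
}

#' Method-of-moments NB dispersion per gene
#'
#' On size-factor-normalized counts, pools the within-condition sample
#' variance across conditions and solves `var = mean + alpha * mean^2` for
#' alpha, floored at `floor`.
#'
#' @param cm a [count_matrix()].
#' @param sf size factors (default computed from `cm`).
#' @param floor smallest admissible dispersion.
#' @return named numeric vector of per-gene dispersions (>= floor).
#' @export
estimate_dispersion <- function(cm, sf = size_factors(cm), floor = 1e-8) {
  y <- sweep(cm$counts, 2, sf, "/")
  cond <- cm$conditions
  reps <- table(cond)
  if (all(reps < 2)) stopf("no condition has >= 2 replicates; supply a fixed dispersion")
  use <- names(reps)[reps >= 2]
  ssq <- 0; df <- 0; wmean <- 0; n <- 0
  for (cc in use) {
    j <- which(cond == cc)
    m <- rowMeans(y[, j, drop = FALSE])
    ssq <- ssq + rowSums((y[, j, drop = FALSE] - m)^2)
    df <- df + length(j) - 1
    wmean <- wmean + m * length(j)
    n <- n + length(j)
  }
  s2 <- ssq / df
  mbar <- wmean / n
  alpha <- ifelse(mbar > 0, (s2 - mbar) / mbar^2, floor)
  setNames(pmax(floor, alpha), rownames(cm$counts))
}

#' Per-gene NB Wald test of a two-condition contrast
#'
#' The log2 fold change MLE is the log2 ratio of size-factor-normalized group
#' means (pseudocount `pseudocount` added to each mean so zeros stay finite).
#' Its standard error comes from the NB variance model
#' `var = mu + alpha mu^2` propagated through the log; the Wald statistic is
#' referenced to a t distribution with the residual degrees of freedom of the
#' two groups, which keeps type-I error near nominal at the small replicate
#' numbers typical of these designs. Genes with all-zero counts in both
#' contrast conditions are excluded from testing and from the BH multiplicity
#' count. Adjusted p-values are Benjamini-Hochberg.
#'
#' @param cm a [count_matrix()].
#' @param contrast character vector `c(numerator, denominator)` of condition
#'   labels; positive LFC means higher in the numerator.
#' @param sf size factors; default computed from `cm`.
#' @param dispersions per-gene dispersions; by default estimated from the two
#'   contrast conditions only, so that the residual degrees of freedom of the
#'   t reference match the information behind the dispersion estimate (this
#'   keeps the test calibrated).
#' @param pseudocount added to normalized group means before the log2 ratio.
#' @return object of class `contrast_result`: a data.frame with columns
#'   `gene, base_mean, lfc_mle, lfc_shrunk, se, p, padj, tested`, plus
#'   attributes `contrast`.
#' @export
lfc_test <- function(cm, contrast, sf = size_factors(cm),
                     dispersions = NULL,
                     pseudocount = 0.5) {
  stopifnot(length(contrast) == 2)
  cond <- cm$conditions
  if (!all(contrast %in% cond))
    stopf("unknown condition label in contrast: %s",
          paste(setdiff(contrast, cond), collapse = ", "))
  j1 <- which(cond == contrast[1]); j2 <- which(cond == contrast[2])
  if (length(j1) < 2 || length(j2) < 2) stopf("both contrast conditions need >= 2 replicates")
  if (is.null(dispersions)) {
    sub <- count_matrix(cm$counts[, c(j1, j2), drop = FALSE], cond[c(j1, j2)])
    dispersions <- estimate_dispersion(sub, sf[c(j1, j2)])
  }
  y <- sweep(cm$counts, 2, sf, "/")
  m1 <- rowMeans(y[, j1, drop = FALSE]); m2 <- rowMeans(y[, j2, drop = FALSE])
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  a <- dispersions[rownames(cm$counts)]
  # Var(normalized count) = mu/sf + alpha mu^2; delta method on log2(mean)
  v1 <- rowSums(vapply(j1, function(j) m1 / sf[j] + a * m1^2, numeric(nrow(y)))) / length(j1)^2
  v2 <- rowSums(vapply(j2, function(j) m2 / sf[j] + a * m2^2, numeric(nrow(y)))) / length(j2)^2
  se <- sqrt(v1 / pmax(m1, pseudocount)^2 + v2 / pmax(m2, pseudocount)^2) / log(2)
  tested <- !(rowSums(cm$counts[, c(j1, j2), drop = FALSE]) == 0)
  dfree <- length(j1) + length(j2) - 2
  tstat <- lfc / se
  p <- 2 * pt(-abs(tstat), df = dfree)
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  res <- data.frame(
    gene = rownames(cm$counts),
    base_mean = (m1 + m2) / 2,
    lfc_mle = lfc, lfc_shrunk = NA_real_, se = se,
    p = p, padj = padj, tested = tested,
    stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- contrast
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Normal-normal posterior mode with a zero-mean prior on the log2 scale:
#' `lfc_shrunk = lfc_mle * (1/se^2) / (1/se^2 + 1/prior_sd^2)`. When
#' `prior_sd` is `NULL` it is estimated by matching the trimmed variance of
#' the MLEs minus the mean squared standard error (floored at 0.05 so the
#' prior never collapses to a point mass).
#'
#' @param result a `contrast_result` from [lfc_test()].
#' @param prior_sd prior standard deviation in log2 units, or `NULL` to
#'   estimate from the data.
#' @return the result with `lfc_shrunk` filled; the estimated/used prior sd
#'   is stored in `attr(result, "prior_sd")`.
#' @export
shrink_lfc <- function(result, prior_sd = NULL) {
  if (!is.null(prior_sd) && prior_sd <= 0) stopf("prior_sd must be positive")
  ok <- result$tested & is.finite(result$se)
  if (is.null(prior_sd)) {
    lfc <- result$lfc_mle[ok]
    q <- quantile(lfc, c(0.05, 0.95), na.rm = TRUE)
    core <- lfc[lfc >= q[1] & lfc <= q[2]]
    v <- var(core) - mean(result$se[ok]^2, na.rm = TRUE)
    prior_sd <- sqrt(max(v, 0.05^2))
  }
  w <- (1 / result$se^2) / (1 / result$se^2 + 1 / prior_sd^2)
  result$lfc_shrunk <- ifelse(ok, result$lfc_mle * w, NA_real_)
  attr(result, "prior_sd") <- prior_sd
  result
}

#' Thresholds for calling differential expression
#'
#' @param lfc_min minimum absolute log2 fold change (strict `>`); the study
#'   convention uses 0.5 by default with 1.0 as the stringent alternative.
#' @param padj_max maximum adjusted p-value (strict `<`), default 0.05.
#' @return list of class `de_thresholds`.
#' @export
de_thresholds <- function(lfc_min = 0.5, padj_max = 0.05) {
  if (lfc_min < 0) stopf("lfc_min must be >= 0")
  if (padj_max <= 0 || padj_max > 1) stopf("padj_max must be in (0, 1]")
  structure(list(lfc_min = lfc_min, padj_max = padj_max), class = "de_thresholds")
}

#' Call differentially expressed genes
#'
#' A gene is called iff `|lfc| > lfc_min` and `padj < padj_max` (both strict).
#'
#' @param result a `contrast_result`; `lfc_shrunk` is used when available
#'   (and `use_shrunk = TRUE`), otherwise the MLE.
#' @param thresholds a [de_thresholds()].
#' @param use_shrunk compare the shrunken LFC against the threshold.
#' @return data.frame with columns `gene`, `called` (logical), `direction`
#'   (`"up"`, `"down"`, or `NA` when not called).
#' @export
call_de <- function(result, thresholds = de_thresholds(), use_shrunk = TRUE) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  lfc <- if (use_shrunk && any(is.finite(result$lfc_shrunk))) result$lfc_shrunk else result$lfc_mle
  called <- !is.na(result$padj) &
    abs(lfc) > thresholds$lfc_min & result$padj < thresholds$padj_max
  data.frame(
    gene = result$gene,
    called = called,
    direction = ifelse(called, ifelse(lfc > 0, "up", "down"), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write a contrast result as TSV
#' @param result a `contrast_result`.
#' @param path output file.
#' @param thresholds optional [de_thresholds()]; when given, `called` and
#'   `direction` columns are appended.
#' @export
write_contrast_tsv <- function(result, path, thresholds = NULL) {
  out <- as.data.frame(result)
  if (!is.null(thresholds)) {
    calls <- call_de(result, thresholds)
    out$called <- calls$called
    out$direction <- calls$direction
  }
  write_tsv_det(out, path)
}
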