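#' Run the end-to-end rescue analysis
#'
#' Simulates (or loads) a knockout-plus-rescue count matrix, runs the
#' differential-expression contrasts, classifies dependent genes, computes
#' the gene rescue capability per construct and the restoration
#' distributions, and persists every intermediate as TSV together with a
#' JSON manifest (parameters, seed, package version) sufficient to reproduce
#' the run byte-identically.
#'
#' @param config list with elements:
#'   `design` — a [rescue_design()] (simulation mode), or
#'   `counts_path`/`samples_path` — TSVs to load instead;
#'   `thresholds` — a [de_thresholds()] (default `de_thresholds()`);
#'   `reference, knockout` — condition labels (defaults `"EV"`, `"KO"`);
#'   `wt_construct` — label of the full-rescue construct (default `"WT"`);
#'   `mutants` — labels of mutant constructs (default: all remaining
#'   conditions); `epsilon` — GRC denominator exclusion (default 1e-6);
#'   `n_bins` — histogram bins (default 20); `prior_sd` — shrinkage prior
#'   (default `NULL` = estimated). A path to a YAML file with these keys is
#'   also accepted.
#' @param output_dir directory for outputs (created if needed).
#' @return invisible list with `dependent_genes`, per-mutant `grc` tables and
#'   `distribution`s, the `contrasts`, and the manifest.
#' @export
run_rescue_pipeline <- function(config, output_dir) {
  config <- load_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- config$thresholds %||% de_thresholds()
  reference <- config$reference %||% "EV"
  knockout <- config$knockout %||% "KO"
  wt <- config$wt_construct %||% "WT"
  epsilon <- config$epsilon %||% 1e-6
  n_bins <- config$n_bins %||% 20

  truth <- NULL
  if (!is.null(config$design)) {
    sim <- simulate_counts(config$design)
    cm <- sim$counts; truth <- sim$truth
    write_counts_tsv(cm, file.path(output_dir, "counts.tsv"),
                     file.path(output_dir, "samples.tsv"))
    write_tsv_det(truth, file.path(output_dir, "truth.tsv"))
  } else if (!is.null(config$counts_path)) {
    cm <- read_counts_tsv(config$counts_path, config$samples_path)
  } else stopf("config needs a design or counts_path/samples_path")

  conds <- unique(unname(cm$conditions))
  for (lbl in c(reference, knockout, wt))
    if (!lbl %in% conds) stopf("condition %s not present in the data", lbl)
  mutants <- config$mutants %||% setdiff(conds, c(reference, knockout, wt))

  sf <- size_factors(cm)
  # One shrinkage prior for the whole experiment family (estimated from the
  # knockout contrast when not supplied): per-contrast priors would shrink
  # the small mutant LFCs harder than the knockout LFCs and bias the GRC
  # ratio; a shared prior makes per-gene shrink factors cancel in the ratio.
  prior_sd <- config$prior_sd %||% NULL
  contrast_vs_ref <- function(cond) {
    res <- lfc_test(cm, c(cond, reference), sf)
    res <- shrink_lfc(res, prior_sd)
    write_contrast_tsv(res, file.path(output_dir, sprintf("contrast_%s_vs_%s.tsv", cond, reference)),
                       thresholds)
    res
  }
  ko_res <- contrast_vs_ref(knockout)
  if (is.null(prior_sd)) prior_sd <- attr(ko_res, "prior_sd")
  wt_res <- contrast_vs_ref(wt)
  mt_res <- lapply(setNames(mutants, mutants), contrast_vs_ref)
  wt_vs_ko <- shrink_lfc(lfc_test(cm, c(wt, knockout), sf), prior_sd)
  write_contrast_tsv(wt_vs_ko, file.path(output_dir, sprintf("contrast_%s_vs_%s.tsv", wt, knockout)),
                     thresholds)

  dep <- classify_dependent_genes(ko_res, wt_vs_ko, thresholds)
  writeLines(dep, file.path(output_dir, "dependent_genes.txt"))

  lfc_of <- function(res) setNames(res$lfc_shrunk, res$gene)
  grc_out <- list(); dist_out <- list()
  for (mt in mutants) {
    tab <- compute_grc(lfc_of(ko_res), lfc_of(wt_res), lfc_of(mt_res[[mt]]),
                       genes = dep, denominator_epsilon = epsilon)
    d <- restoration_distribution(tab, n_bins)
    write_grc_tsv(tab, d, file.path(output_dir, sprintf("grc_%s.tsv", mt)),
                  file.path(output_dir, sprintf("grc_hist_%s.tsv", mt)))
    grc_out[[mt]] <- tab; dist_out[[mt]] <- d
  }

  manifest <- list(
    pipeline = "rescue", package_version = as.character(packageVersion("pauseRescue")),
    seed = if (!is.null(config$design)) config$design$seed else NA,
    parameters = serializable_config(config),
    outputs = list.files(output_dir)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dependent_genes = dep, grc = grc_out, distributions = dist_out,
                 contrasts = c(list(ko = ko_res, wt = wt_res, wt_vs_ko = wt_vs_ko), mt_res),
                 truth = truth, manifest = manifest))
}

#' Run the end-to-end pausing analysis
#'
#' Simulates (or loads) alignments, applies the MAPQ filter, computes the
#' traveling-ratio table with status accounting, the metagene profile and the
#' TSS / gene-body window signals, and persists outputs (TSV + bedGraph)
#' together with a JSON manifest.
#'
#' @param config list with elements: `design` — a [pausing_design()]
#'   (simulation mode), or `alignments_path` + `genes_path` to load;
#'   `tr_config` — a [tr_config()]; `metagene_config` — a
#'   [metagene_config()]; `tss_window`/`gb_window` — offsets relative to the
#'   TSS (defaults `c(-500, 500)` and `c(500, 2500)`). A YAML path is also
#'   accepted.
#' @param output_dir directory for outputs.
#' @return invisible list with `tr_table`, `metagene`, `tss_signal`,
#'   `gb_signal`, and the manifest.
#' @export
run_pausing_pipeline <- function(config, output_dir) {
  config <- load_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tcfg <- config$tr_config %||% tr_config()
  mcfg <- config$metagene_config %||% metagene_config()
  tss_w <- config$tss_window %||% c(-500, 500)
  gb_w <- config$gb_window %||% c(500, 2500)

  if (!is.null(config$design)) {
    genes <- config$design$gene_models
    aln_all <- simulate_alignments(config$design)
    sam <- file.path(output_dir, "alignments.sam")
    write_sam(aln_all, sam)
    write_gene_bed(genes, file.path(output_dir, "genes.bed"))
    aln <- suppressMessages(read_alignments(sam, tcfg$mapq_min))
  } else if (!is.null(config$alignments_path)) {
    genes <- read_gene_models(config$genes_path)
    aln <- suppressMessages(read_alignments(config$alignments_path, tcfg$mapq_min))
  } else stopf("config needs a design or alignments_path/genes_path")

  empty <- length(aln) == 0
  if (empty) {
    tr_tab <- data.frame(gene = genes$gene_id, tssr_signal = 0, gbr_signal = 0,
                         tr = NA_real_, status = "filtered_weak",
                         stringsAsFactors = FALSE)
    prof <- numeric(mcfg$upstream + mcfg$body_target + mcfg$downstream_of_tes)
    tss_sig <- data.frame(gene = genes$gene_id, signal = 0)
    gb_sig <- data.frame(gene = genes$gene_id, signal = 0)
  } else {
    tr_tab <- traveling_ratio(genes, aln, tcfg)
    track <- coverage_track(aln, bin = mcfg$bin)
    write_bedgraph(track, file.path(output_dir, "coverage.bedGraph"))
    prof <- metagene_profile(track, genes, mcfg)
    tss_sig <- window_signal(aln, genes, tss_w)
    gb_sig <- window_signal(aln, genes, gb_w)
  }
  write_tsv_det(tr_tab, file.path(output_dir, "tr_table.tsv"))
  write_tsv_det(data.frame(position = seq_along(prof), rpkm = as.numeric(prof)),
                file.path(output_dir, "metagene.tsv"))
  write_tsv_det(tss_sig, file.path(output_dir, "tss_window.tsv"))
  write_tsv_det(gb_sig, file.path(output_dir, "gb_window.tsv"))

  manifest <- list(
    pipeline = "pausing", package_version = as.character(packageVersion("pauseRescue")),
    seed = if (!is.null(config$design)) config$design$seed else NA,
    n_alignments_kept = length(aln),
    status_counts = as.list(table(tr_tab$status)),
    parameters = serializable_config(config),
    outputs = list.files(output_dir),
    all_filtered = empty
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tr_table = tr_tab, metagene = prof, tss_signal = tss_sig,
                 gb_signal = gb_sig, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    # rebuild typed components from flat keys
    if (!is.null(config$design) && !is.null(config$design$kind)) {
      d <- config$design
      config$design <- if (d$kind == "rescue") {
        do.call(rescue_design, d[setdiff(names(d), "kind")])
      } else stopf("only rescue designs can be rebuilt from YAML")
    }
    if (!is.null(config$thresholds))
      config$thresholds <- do.call(de_thresholds, config$thresholds)
    if (!is.null(config$tr_config))
      config$tr_config <- do.call(tr_config, config$tr_config)
    if (!is.null(config$metagene_config))
      config$metagene_config <- do.call(metagene_config, config$metagene_config)
  }
  config
}

# a plain-list rendering of the config for the manifest (drops GRanges)
serializable_config <- function(config) {
  strip <- function(x) {
    if (inherits(x, "GRanges")) return(sprintf("<%d gene models>", length(x)))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass_all(config))
}

unclass_all <- function(x) {
  if (is.list(x) && !inherits(x, "GRanges")) {
    x <- unclass(x)
    lapply(x, function(e) if (is.list(e) && !inherits(e, "GRanges")) unclass_all(e) else e)
  } else x
}
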