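#' Simulate an exponential growth curve
#'
#' `reading(t) = n0 * 2^(t / doubling_time) * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`.
#'
#' @param n0 initial reading (> 0).
#' @param doubling_time doubling time in hours (> 0).
#' @param timepoints strictly increasing hours.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @return data.frame `time, reading`.
#' @export
simulate_growth_curve <- function(n0, doubling_time, timepoints, noise_cv = 0, seed = 1) {
  if (doubling_time <= 0) stopf("doubling_time must be positive")
  if (n0 <= 0) stopf("n0 must be positive")
  if (any(diff(timepoints) <= 0)) stopf("timepoints must be strictly increasing")
  mu <- n0 * 2^(timepoints / doubling_time)
  eps <- if (noise_cv > 0) with_seed(seed, rnorm(length(timepoints), 0, noise_cv)) else 0
  data.frame(time = timepoints, reading = mu * (1 + eps))
}

#' Fit an exponential (Malthusian) growth model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of `N(t) = n0 * exp(k * t)`
#' on the raw readings, initialized from the log-linear regression; doubling
#' time is `ln(2) / k`.
#' On non-convergence the log-linear fit is returned with `converged = FALSE`.
#' A non-positive growth rate leaves the doubling time `NA` (flagged).
#'
#' @param timepoints hours (>= 3 points).
#' @param readings positive readings, same length.
#' @return list of class `growth_fit`: `n0, k, doubling_time, residual_sse,
#'   converged`.
#' @export
fit_exponential <- function(timepoints, readings) {
  if (length(timepoints) < 3) stopf("need at least 3 timepoints")
  if (length(readings) != length(timepoints)) stopf("lengths differ")
  if (any(readings <= 0)) stopf("readings must be positive")
  ll <- lm(log(readings) ~ timepoints)
  start <- list(n0 = exp(coef(ll)[[1]]), k = coef(ll)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(readings ~ n0 * exp(k * timepoints), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    n0 <- start$n0; k <- start$k
    sse <- sum((readings - n0 * exp(k * timepoints))^2)
    converged <- FALSE
  } else {
    cf <- coef(fit)
    n0 <- cf[["n0"]]; k <- cf[["k"]]
    sse <- sum(residuals(fit)^2)
    converged <- TRUE
  }
  # growth rates below 1e-10/h (doubling time ~ a million years) are treated
  # as no growth: doubling time undefined
  td <- if (k > 1e-10) log(2) / k else NA_real_
  structure(list(n0 = n0, k = k, doubling_time = td,
                 residual_sse = sse, converged = converged),
            class = "growth_fit")
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference gene)`; dCt values are
#' averaged per condition, then `ddCt = dCt(condition) - dCt(control)` and
#' relative expression is `2^-ddCt`. The control condition maps to 1 by
#' construction.
#'
#' @param ct_table data.frame with columns `sample, condition, gene, ct`.
#' @param reference_gene internal control gene (e.g. 18S rRNA), measured in
#'   every sample.
#' @param control_condition condition used as the ddCt baseline.
#' @return data.frame `gene, condition, delta_ct, delta_delta_ct,
#'   relative_expression`.
#' @export
ddct <- function(ct_table, reference_gene, control_condition) {
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(ct_table))) stopf("ct_table needs columns: %s", paste(need, collapse = ", "))
  ref <- ct_table[ct_table$gene == reference_gene, c("sample", "ct")]
  if (!all(unique(ct_table$sample) %in% ref$sample))
    stopf("reference gene %s missing in some samples", reference_gene)
  if (!control_condition %in% ct_table$condition)
    stopf("control condition %s not present", control_condition)
  tg <- ct_table[ct_table$gene != reference_gene, , drop = FALSE]
  tg$ref_ct <- ref$ct[match(tg$sample, ref$sample)]
  tg$delta_ct <- tg$ct - tg$ref_ct
  agg <- stats::aggregate(delta_ct ~ gene + condition, data = tg, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$gene), function(d) {
    base <- d$delta_ct[d$condition == control_condition]
    if (length(base) != 1) stopf("control condition missing for gene %s", d$gene[1])
    d$delta_delta_ct <- d$delta_ct - base
    d$relative_expression <- 2^(-d$delta_delta_ct)
    d
  }))
  rownames(out) <- NULL
  out[, c("gene", "condition", "delta_ct", "delta_delta_ct", "relative_expression")]
}
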