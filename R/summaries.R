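# Summary statistics from posterior curve samples: AUC over the tested doses,
# IC50 as the first down-crossing of 50% viability on an extended grid, and
# the observation/estimation decomposition of replicate variability.

# Rescaled-dose grid extending to 10x the maximum tested concentration.
extended_grid <- function(experiment, grid_size = 200L) {
  dmax <- experiment$max_log2_dose
  ext <- (dmax + log2(10) + 1) / (dmax + 1)
  sort(unique(c(experiment$dprime,
                seq(min(experiment$dprime), ext, length.out = grid_size))))
}

#' AUC mean and SD from curve samples at the tested doses
#'
#' On the log2 dose scale the tested doses are (near) equally spaced, so the
#' area under the normalised curve is the plain mean of the viabilities:
#' \code{AUC = (1/n) sum(y_m)}, giving 1 for a flat non-responder and values
#' toward 0 for a complete kill. AUC never uses extrapolated dose columns.
#'
#' @param samples matrix of curve samples, columns exactly the tested doses.
#' @return list with \code{auc_mean} and \code{auc_sd} (sample SD across
#'   curves; 0 when only one curve).
#' @export
auc_from_samples <- function(samples) {
  samples <- rbind(samples)
  per_sample <- rowMeans(samples)
  list(auc_mean = mean(per_sample),
       auc_sd = if (nrow(samples) > 1L) stats::sd(per_sample) else 0)
}

#' IC50 statistics from curve samples on an extended grid
#'
#' For each sampled curve the IC50 is the first dose (left to right, linear
#' interpolation between grid points) at which viability reaches 0.5. Curves
#' that never reach 0.5 anywhere on the grid are non-crossing and are excluded
#' from the mean/SD; their share is reported via \code{crossing_fraction}.
#' With no crossing curves at all, the IC50 statistics are NaN.
#'
#' @param samples \code{N x length(grid)} matrix of viability curves.
#' @param grid rescaled dose grid (includes extrapolation range).
#' @param max_tested_dprime rescaled maximum tested dose (normally 1).
#' @return list with \code{ic50_mean}, \code{ic50_sd} (rescaled-dose units),
#'   \code{crossing_fraction}, \code{within_range} (posterior-mean IC50 at or
#'   below the maximum tested dose), and \code{ic50_samples} (crossing draws).
#' @export
ic50_from_samples <- function(samples, grid, max_tested_dprime = 1) {
  samples <- rbind(samples)
  crossings <- apply(samples, 1L, function(yy) {
    idx <- which(yy <= 0.5)
    if (!length(idx)) return(NA_real_)
    i <- idx[1L]
    if (i == 1L) return(grid[1L])
    grid[i - 1L] + (0.5 - yy[i - 1L]) * (grid[i] - grid[i - 1L]) /
      (yy[i] - yy[i - 1L])
  })
  ok <- crossings[!is.na(crossings)]
  cf <- length(ok) / nrow(samples)
  if (!length(ok))
    return(list(ic50_mean = NaN, ic50_sd = NaN, crossing_fraction = 0,
                within_range = FALSE, ic50_samples = numeric(0)))
  list(ic50_mean = mean(ok),
       ic50_sd = if (length(ok) > 1L) stats::sd(ok) else 0,
       crossing_fraction = cf,
       within_range = mean(ok) <= max_tested_dprime,
       ic50_samples = ok)
}

#' Posterior response summary for one experiment
#'
#' Samples \code{N} curves from the fitted posterior on a grid spanning the
#' tested range and its extrapolation to 10x the maximum concentration,
#' extracts per-curve AUC (tested doses only) and IC50 (extended grid), and
#' reports posterior means and SDs, with IC50 back-transformed to log10
#' micromolar.
#'
#' @param posterior a [fit_gp()] result.
#' @param experiment the matching [dose_response_experiment()]; defaults to
#'   the one stored in the posterior.
#' @param N number of posterior curve samples.
#' @param seed RNG seed; fixed seed gives an identical summary.
#' @param grid_size grid resolution over the extended dose range.
#' @param keep_samples retain the per-curve log10(IC50) draws in the result.
#' @return object of class \code{"response_summary"}.
#' @export
summarize_experiment <- function(posterior, experiment = posterior$experiment,
                                 N = 100L, seed = 1L, grid_size = 200L,
                                 keep_samples = FALSE) {
  grid <- extended_grid(experiment, grid_size)
  curves <- sample_curves(posterior, grid, N = N, seed = seed)
  tested_cols <- match(experiment$dprime, grid)
  auc <- auc_from_samples(curves[, tested_cols, drop = FALSE])
  ic <- ic50_from_samples(curves, grid, max_tested_dprime = 1)
  ic_log10 <- dprime_to_log10uM(ic$ic50_samples, experiment$max_log2_dose)
  scale <- (experiment$max_log2_dose + 1) * log10(2)
  out <- list(
    cell_line_id = experiment$cell_line_id,
    drug_id = experiment$drug_id,
    ic50_mean_log10uM = if (length(ic_log10)) mean(ic_log10) else NaN,
    ic50_sd = if (length(ic_log10) > 1L) stats::sd(ic_log10)
              else if (length(ic_log10) == 1L) 0 else NaN,
    auc_mean = auc$auc_mean,
    auc_sd = auc$auc_sd,
    crossing_fraction = ic$crossing_fraction,
    within_range = ic$within_range,
    qc_spearman = as.numeric(qc_spearman(experiment)),
    n_samples = as.integer(N),
    max_log10_dose = experiment$max_log2_dose * log10(2),
    rescale_factor = scale
  )
  if (keep_samples) out$ic50_samples_log10uM <- ic_log10
  structure(out, class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf(
    "<response_summary> %s x %s: log10(IC50) = %.3f (sd %.3f), AUC = %.3f (sd %.3f)\n  crossing %.0f%%, %s range, QC rho = %.2f\n",
    x$cell_line_id, x$drug_id, x$ic50_mean_log10uM, x$ic50_sd, x$auc_mean,
    x$auc_sd, 100 * x$crossing_fraction,
    if (x$within_range) "within" else "beyond", x$qc_spearman))
  invisible(x)
}

#' Observation vs estimation uncertainty across replicates
#'
#' For replicates of one (drug, cell line) condition: the observation
#' uncertainty is the SD across replicates of the per-replicate posterior-mean
#' log10(IC50); the estimation uncertainty is the mean across replicates of
#' the per-replicate posterior SD. Replicates whose curves never cross 50\%
#' viability carry no IC50 and are excluded (counted in the result).
#'
#' @param summaries list of [summarize_experiment()] results fitted with
#'   \code{keep_samples = TRUE} (pooled density needs the draws).
#' @return object of class \code{"replicate_uncertainty"} with
#'   \code{observation_uncertainty}, \code{estimation_uncertainty},
#'   \code{n_replicates}, \code{n_excluded}, \code{pooled_samples}.
#' @export
replicate_uncertainty <- function(summaries) {
  cross <- vapply(summaries, function(s) s$crossing_fraction > 0, logical(1L))
  n_excluded <- sum(!cross)
  if (n_excluded)
    warning(sprintf("%d replicate(s) with no crossing samples excluded",
                    n_excluded))
  summaries <- summaries[cross]
  if (length(summaries) < 2L)
    stop_gpdrc("gpdrc_value_error",
               "replicate decomposition needs at least 2 crossing replicates")
  means <- vapply(summaries, function(s) s$ic50_mean_log10uM, numeric(1L))
  sds <- vapply(summaries, function(s) s$ic50_sd, numeric(1L))
  pooled <- unlist(lapply(summaries, function(s) s$ic50_samples_log10uM))
  structure(list(
    observation_uncertainty = stats::sd(means),
    estimation_uncertainty = mean(sds),
    n_replicates = length(summaries),
    n_excluded = n_excluded,
    pooled_samples = pooled
  ), class = "replicate_uncertainty")
}

#' Fit a collection of experiments and build a response table
#'
#' Runs either the GP pipeline ([fit_gp()] + [summarize_experiment()]) or the
#' sigmoid baseline ([fit_sigmoid()]) over a list of experiments and returns
#' one response-table row per experiment. For the sigmoid, the IC50 is the
#' fitted position parameter (the curve crosses 0.5 there by construction)
#' and the AUC is the mean of the fitted curve at the tested doses, matching
#' the GP's AUC functional; \code{bootstrap = TRUE} adds shared-shape
#' bootstrap SDs per drug (needs >= 10 cell lines per drug).
#'
#' @param experiments list of [dose_response_experiment()]s.
#' @param method \code{"gp"} or \code{"sigmoid"}.
#' @param N posterior samples per experiment (GP).
#' @param seed base seed; experiment i uses \code{seed + i}.
#' @param bootstrap sigmoid only: compute bootstrap IC50 SDs.
#' @param ... passed on to [fit_gp()].
#' @return a validated response table (data.frame).
#' @export
fit_experiments <- function(experiments, method = c("gp", "sigmoid"),
                            N = 100L, seed = 1L, bootstrap = FALSE, ...) {
  method <- match.arg(method)
  rows <- lapply(seq_along(experiments), function(i) {
    e <- experiments[[i]]
    if (method == "gp") {
      s <- summarize_experiment(fit_gp(e, ...), e, N = N, seed = seed + i)
      data.frame(cell_line_id = e$cell_line_id, drug_id = e$drug_id,
                 ic50_mean_log10uM = s$ic50_mean_log10uM, ic50_sd = s$ic50_sd,
                 auc_mean = s$auc_mean, auc_sd = s$auc_sd,
                 crossing_fraction = s$crossing_fraction,
                 within_range = s$within_range, qc_spearman = s$qc_spearman,
                 method = "gp", stringsAsFactors = FALSE)
    } else {
      fit <- fit_sigmoid(e)
      data.frame(cell_line_id = e$cell_line_id, drug_id = e$drug_id,
                 ic50_mean_log10uM = dprime_to_log10uM(fit$p, e$max_log2_dose),
                 ic50_sd = NaN,
                 auc_mean = mean(sigmoid_curve(e$dprime, fit)),
                 auc_sd = NaN, crossing_fraction = 1,
                 within_range = fit$p <= 1,
                 qc_spearman = as.numeric(qc_spearman(e)),
                 method = "sigmoid", stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  if (method == "sigmoid" && bootstrap) {
    for (drug in unique(tab$drug_id)) {
      idx <- which(tab$drug_id == drug)
      bs <- bootstrap_ic50_sd(experiments[idx], seed = seed)
      tab$ic50_sd[idx] <- bs$ic50_sd[match(tab$cell_line_id[idx],
                                           bs$cell_line_id)]
    }
  }
  validate_response_table(tab)
}
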