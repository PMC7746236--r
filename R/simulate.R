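# Synthetic screen generator. Viabilities are drawn from the same Beta-mixture
# observation model the GP assumes (response component around a ground-truth
# sigmoid, rare high-viability outliers), then converted back to raw well
# intensities with simulated blank/control wells so the preprocessing path is
# exercised end to end. Truth objects are test-only and never consumed by
# fitting code.

#' Noise specification for the synthetic generator
#'
#' Defaults mirror the screening calibration of the observation model:
#' response-component Beta scale 50, outlier mean 0.9, outlier rate 0.001.
#'
#' @param beta_scale Beta scale of the response noise (larger = less noise).
#' @param outlier_rate probability a well is replaced by an outlier draw,
#'   in \[0, 0.2\].
#' @param outlier_mu outlier mean viability.
#' @param outlier_scale Beta scale of the outlier component.
#' @param well_sdlog lognormal multiplicative intensity noise per well.
#' @param trend_sd scale (viability units) of a smooth random distortion of
#'   the whole curve, redrawn per experiment: emulates the systematic
#'   artifacts of poor-quality assays (drifting readouts, viability rising
#'   with dose), which scatter is too unstructured to represent. 0 disables.
#' @return named list.
#' @export
noise_spec <- function(beta_scale = 50, outlier_rate = 0.001, outlier_mu = 0.9,
                       outlier_scale = 11, well_sdlog = 0.05, trend_sd = 0) {
  stopifnot(beta_scale > 0, outlier_rate >= 0, outlier_rate <= 0.2,
            outlier_mu > 0, outlier_mu < 1, well_sdlog >= 0, trend_sd >= 0)
  list(beta_scale = beta_scale, outlier_rate = outlier_rate,
       outlier_mu = outlier_mu, outlier_scale = outlier_scale,
       well_sdlog = well_sdlog, trend_sd = trend_sd)
}

#' Titration design for a synthetic experiment
#'
#' @param n_points number of titration points (5 to 9 typical).
#' @param fold dilution factor between consecutive doses (2 or 4).
#' @param top_dose_uM maximum concentration in micromolar.
#' @return named list.
#' @export
dose_design <- function(n_points = 9L, fold = 2, top_dose_uM = 10) {
  stopifnot(n_points >= 2L, fold > 1, top_dose_uM > 0)
  list(n_points = as.integer(n_points), fold = fold, top_dose_uM = top_dose_uM)
}

# Beta_mu draw with mean mu and scale s.
rbeta_mu <- function(n, mu, s) stats::rbeta(n, mu * s, (1 - mu) * s)

#' Simulate one dose-response experiment with known truth
#'
#' Ground truth is a sigmoid with shape \code{s} and position \code{p} on the
#' rescaled dose axis. Viabilities are Beta-mixture draws around the true
#' curve; raw intensities use control mean 1e5, blank mean 1e3 and
#' multiplicative lognormal well noise. Fully reproducible per seed.
#'
#' @param s,p true sigmoid shape and position (rescaled-dose units).
#' @param design a [dose_design()].
#' @param noise a [noise_spec()].
#' @param seed RNG seed.
#' @param cell_line_id,drug_id,batch_id identifiers for the emitted rows.
#' @return list with \code{raw} (raw screen table rows incl. 3 blank and 3
#'   control wells), \code{experiment} (the normalised truth-free
#'   [dose_response_experiment()] derived from those rows) and \code{truth}
#'   (s, p, true log10 IC50, responder class, seed).
#' @export
simulate_experiment <- function(s, p, design = dose_design(),
                                noise = noise_spec(), seed = 1L,
                                cell_line_id = "CL1", drug_id = "D1",
                                batch_id = "B1") {
  set.seed(seed)
  doses <- design$top_dose_uM / design$fold^((design$n_points - 1L):0L)
  dprime <- rescale_doses(doses)
  mu <- sigmoid_curve(as.numeric(dprime), s, p)
  if (is.null(noise$trend_sd)) noise$trend_sd <- 0
  if (noise$trend_sd > 0) {
    # smooth systematic artifact: random tilt plus one low-frequency bump
    z <- (dprime - min(dprime)) / diff(range(dprime))
    mu <- mu + stats::rnorm(1L, 0, noise$trend_sd) * (z - 0.5) +
      stats::rnorm(1L, 0, noise$trend_sd) *
        cos(pi * z + stats::runif(1L, 0, 2 * pi))
  }
  mu <- clip_unit(mu, 1e-4)
  V <- rbeta_mu(length(mu), mu, noise$beta_scale)
  is_out <- stats::runif(length(mu)) < noise$outlier_rate
  if (any(is_out))
    V[is_out] <- rbeta_mu(sum(is_out), noise$outlier_mu, noise$outlier_scale)
  B_true <- 1e3; C_true <- 1e5
  lnoise <- function(k) stats::rlnorm(k, -noise$well_sdlog^2 / 2, noise$well_sdlog)
  raw <- rbind(
    data.frame(cell_line_id = cell_line_id, drug_id = drug_id,
               batch_id = batch_id, well_type = "treated", dose_uM = doses,
               intensity = (B_true + V * (C_true - B_true)) * lnoise(length(V)),
               stringsAsFactors = FALSE),
    data.frame(cell_line_id = cell_line_id, drug_id = "-", batch_id = batch_id,
               well_type = "blank", dose_uM = NA_real_,
               intensity = B_true * lnoise(3L), stringsAsFactors = FALSE),
    data.frame(cell_line_id = cell_line_id, drug_id = "-", batch_id = batch_id,
               well_type = "neg_control", dose_uM = NA_real_,
               intensity = C_true * lnoise(3L), stringsAsFactors = FALSE))
  class(raw) <- c("raw_screen_table", "data.frame")
  experiment <- screen_experiments(raw)[[1L]]
  max_d <- attr(dprime, "max_log2_dose")
  truth <- list(s = s, p = p,
                true_log10_ic50 = dprime_to_log10uM(p, max_d),
                responder_class = if (p <= 1) "within_range" else "beyond_range",
                seed = seed)
  list(raw = raw, experiment = experiment, truth = truth)
}

#' Simulate a cell-line panel with a mutation-linked IC50 shift
#'
#' Generates \code{n_cell_lines} cell lines across \code{tissue_count}
#' tissues, assigns a binary feature with probability \code{mutant_fraction},
#' and shifts mutant cell lines' true log10 IC50 by \code{beta_true} (plus a
#' N(0, 0.3) tissue offset when several tissues are present). One experiment
#' per (cell line, drug) via [simulate_experiment()].
#'
#' @param n_cell_lines,n_drugs panel dimensions.
#' @param beta_true mutation effect on log10(IC50), micromolar scale.
#' @param mutant_fraction probability a cell line carries the feature.
#' @param tissue_count number of tissue labels.
#' @param base_p mean wild-type position (rescaled-dose units).
#' @param base_p_sd between-cell-line SD of the position.
#' @param s_range true shape is drawn uniformly from this range.
#' @param design,noise generator settings.
#' @param seed RNG seed.
#' @return list with \code{experiments} (list), \code{bem}
#'   (binary_event_matrix with feature \code{"MUT"}), \code{truth}
#'   (per-cell-line data.frame plus \code{beta_true}).
#' @export
simulate_panel <- function(n_cell_lines = 50L, n_drugs = 1L, beta_true = -1,
                           mutant_fraction = 0.5, tissue_count = 1L,
                           base_p = 0.6, base_p_sd = 0.15,
                           s_range = c(0.08, 0.2), design = dose_design(),
                           noise = noise_spec(), seed = 1L) {
  stopifnot(mutant_fraction > 0, mutant_fraction < 1)
  set.seed(seed)
  ids <- sprintf("CL%03d", seq_len(n_cell_lines))
  tissue <- sprintf("T%d", 1L + (seq_len(n_cell_lines) - 1L) %% tissue_count)
  z <- stats::rbinom(n_cell_lines, 1L, mutant_fraction)
  # guarantee both groups exist
  if (all(z == 1)) z[1L] <- 0L
  if (all(z == 0)) z[n_cell_lines] <- 1L
  tissue_offset <- if (tissue_count > 1L)
    stats::rnorm(tissue_count, 0, 0.3) else 0
  # convert a log10-uM shift into rescaled-dose units
  d_top <- log2(design$top_dose_uM)
  to_dprime <- 1 / ((d_top + 1) * log10(2))
  truth_rows <- list(); experiments <- list()
  for (i in seq_len(n_cell_lines)) {
    p0 <- stats::rnorm(1L, base_p, base_p_sd)
    shift_log10 <- beta_true * z[i] +
      if (tissue_count > 1L) tissue_offset[as.integer(sub("T", "", tissue[i]))] else 0
    p_i <- p0 + shift_log10 * to_dprime
    for (j in seq_len(n_drugs)) {
      s_ij <- stats::runif(1L, s_range[1L], s_range[2L])
      sim <- simulate_experiment(s_ij, p_i, design, noise,
                                 seed = seed + 131L * i + 7919L * j,
                                 cell_line_id = ids[i],
                                 drug_id = sprintf("DRUG%02d", j))
      experiments[[length(experiments) + 1L]] <- sim$experiment
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        cell_line_id = ids[i], drug_id = sprintf("DRUG%02d", j), z = z[i],
        tissue = tissue[i], s = s_ij, p = p_i,
        true_log10_ic50 = sim$truth$true_log10_ic50,
        stringsAsFactors = FALSE)
    }
  }
  values <- matrix(z, ncol = 1L, dimnames = list(ids, "MUT"))
  bem <- structure(list(cell_line_ids = ids, feature_ids = "MUT",
                        values = values, cancer_type = tissue),
                   class = "binary_event_matrix")
  list(experiments = experiments, bem = bem,
       truth = list(table = do.call(rbind, truth_rows), beta_true = beta_true))
}

#' Simulate a replicate study
#'
#' Emulates a replication screen: \code{n_drugs x n_cell_lines} conditions,
#' each measured in \code{n_replicates} batches. Replicates share the
#' condition's true curve up to a batch-level potency drift of
#' \code{N(0, batch_effect_sd^2)} in log10 concentration units, applied as a
#' shift to the true position. Conditions vary in position (within and
#' beyond the tested range), slope (shallow partial responders are the
#' high-estimation-uncertainty regime) and assay quality (noise scale and
#' outlier rate).
#'
#' @param n_drugs,n_cell_lines,n_replicates study dimensions.
#' @param batch_effect_sd SD of the batch-level potency drift, log10
#'   concentration units.
#' @param p_range true positions drawn uniformly from this range (values
#'   above 1 are beyond-range conditions).
#' @param s_range true shapes drawn uniformly from this range; the upper end
#'   produces shallow partial responders whose crossing point is genuinely
#'   uncertain, the high-estimation-uncertainty regime of real screens.
#' @param beta_scale_range per-condition response-noise scale drawn
#'   log-uniformly from this range (the low end emulates poor-quality assays).
#' @param outlier_rate_range per-condition outlier-well rate drawn uniformly
#'   from this range; outlier-ridden conditions reproduce the poor-readout
#'   tail of real screens, where curve fits are genuinely uncertain.
#' @param trend_sd_range per-condition scale of the smooth systematic
#'   artifact (see [noise_spec()]), drawn uniformly from this range: the
#'   shared pathology that makes a condition's curve fits both individually
#'   uncertain and poorly reproducible across replicates.
#' @param design generator design (7-point half-log-like default).
#' @param seed RNG seed.
#' @return list with \code{conditions} (data.frame of truth per condition)
#'   and \code{replicates}: per condition, a list of
#'   [dose_response_experiment()]s, one per batch.
#' @export
simulate_replicate_study <- function(n_drugs = 26L, n_cell_lines = 10L,
                                     n_replicates = 8L, batch_effect_sd = 0.2,
                                     p_range = c(0.35, 1.4),
                                     s_range = c(0.08, 0.6),
                                     beta_scale_range = c(3, 200),
                                     outlier_rate_range = c(0, 0.15),
                                     trend_sd_range = c(0, 0.2),
                                     design = dose_design(n_points = 7L),
                                     seed = 1L) {
  stopifnot(batch_effect_sd >= 0)
  set.seed(seed)
  conds <- expand.grid(drug_id = sprintf("DRUG%02d", seq_len(n_drugs)),
                       cell_line_id = sprintf("CL%02d", seq_len(n_cell_lines)),
                       stringsAsFactors = FALSE)
  conds$p <- stats::runif(nrow(conds), p_range[1L], p_range[2L])
  conds$s <- stats::runif(nrow(conds), s_range[1L], s_range[2L])
  conds$beta_scale <- exp(stats::runif(nrow(conds), log(beta_scale_range[1L]),
                                       log(beta_scale_range[2L])))
  conds$outlier_rate <- stats::runif(nrow(conds), outlier_rate_range[1L],
                                     outlier_rate_range[2L])
  conds$trend_sd <- stats::runif(nrow(conds), trend_sd_range[1L],
                                 trend_sd_range[2L])
  d_top <- log2(design$top_dose_uM)
  conds$true_log10_ic50 <- (conds$p * (d_top + 1) - 1) * log10(2)
  replicates <- vector("list", nrow(conds))
  # convert the log10 drift into rescaled-dose units for this design
  drift_dprime <- batch_effect_sd / ((d_top + 1) * log10(2))
  for (k in seq_len(nrow(conds))) {
    set.seed(seed + 17L * k)
    shifts <- stats::rnorm(n_replicates, 0, drift_dprime)
    replicates[[k]] <- lapply(seq_len(n_replicates), function(b) {
      simulate_experiment(conds$s[k], conds$p[k] + shifts[b], design,
                          noise_spec(beta_scale = conds$beta_scale[k],
                                     outlier_rate = conds$outlier_rate[k],
                                     trend_sd = conds$trend_sd[k]),
                          seed = seed + 17L * k + b,
                          cell_line_id = conds$cell_line_id[k],
                          drug_id = conds$drug_id[k],
                          batch_id = sprintf("B%d", b))$experiment
    })
  }
  list(conditions = conds, replicates = replicates)
}
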