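#' Two-parameter sigmoid dose-response curve
#'
#' \code{f(d) = 1 / (1 + exp((d - p) / s))} on the rescaled dose axis: shape
#' \code{s > 0} controls steepness, position \code{p} is the dose at which
#' viability is exactly 0.5, i.e. the curve's IC50 in rescaled units.
#'
#' @param d rescaled dose value(s).
#' @param params a \code{sigmoid_params} object from [fit_sigmoid()], or a
#'   shape scalar when \code{p} is given.
#' @param p position parameter when \code{params} is passed as a shape scalar.
#' @return viability in (0, 1).
#' @examples
#' sigmoid_curve(0.6, params = list(s = 0.2, p = 0.6))  # 0.5
#' @export
sigmoid_curve <- function(d, params, p = NULL) {
  if (is.null(p)) {
    s <- params$s
    p <- params$p
  } else {
    s <- params
  }
  if (s <= 0) stop_gpdrc("gpdrc_value_error", "shape parameter s must be > 0")
  1 / (1 + exp((d - p) / s))
}

sigmoid_rss <- function(par, d, y) {
  sum((y - 1 / (1 + exp((d - par[2L]) / par[1L])))^2)
}

#' Fit the two-parameter sigmoid by multi-start least squares
#'
#' Minimises unweighted squared error on viability over (shape, position)
#' with bounded L-BFGS-B from a grid of starting values
#' (p in \{0.2, 0.5, 0.8, 1.2, 2.0\} crossed with s in \{0.05, 0.2, 1.0\}),
#' bounds s in \[1e-3, 10\], p in \[-5, 10\]. A non-responder (flat viability
#' near 1) drives the position estimate beyond the tested range (p > 1).
#'
#' @param experiment a [dose_response_experiment()] with at least 4 doses, or
#'   a numeric vector of rescaled doses when \code{viability} is given.
#' @param viability optional viability vector aligned to the doses.
#' @param shape optional fixed shape: only the position is optimised (used by
#'   the shared-shape bootstrap).
#' @return object of class \code{"sigmoid_params"}: list with \code{s},
#'   \code{p}, \code{converged}, \code{rss}.
#' @export
fit_sigmoid <- function(experiment, viability = NULL, shape = NULL) {
  if (is.null(viability)) {
    d <- experiment$dprime
    y <- experiment$viability
  } else {
    d <- as.numeric(experiment)
    y <- viability
  }
  if (length(d) < 4L)
    stop_gpdrc("gpdrc_value_error", "sigmoid fit needs at least 4 dose points")

  if (!is.null(shape)) {
    opt <- stats::optimize(function(p) sigmoid_rss(c(shape, p), d, y),
                           interval = c(-5, 10), tol = 1e-9)
    return(structure(list(s = shape, p = opt$minimum, converged = TRUE,
                          rss = opt$objective), class = "sigmoid_params"))
  }

  starts <- expand.grid(s = c(0.05, 0.2, 1.0), p = c(0.2, 0.5, 0.8, 1.2, 2.0))
  best <- NULL
  best_ok <- Inf  # best RSS among cleanly converged starts
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$s[i], starts$p[i]), sigmoid_rss, d = d, y = y,
                   method = "L-BFGS-B", lower = c(1e-3, -5), upper = c(10, 10),
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) best_ok <- min(best_ok, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_gpdrc("gpdrc_fit_error", "sigmoid optimisation failed at every start")
  # L-BFGS-B reports an abnormal line search (code 52) at near-perfect fits
  # where the RSS improvement underflows; the fit still counts as converged
  # when a cleanly converged start corroborates the same minimum.
  conv <- best$convergence == 0L ||
    best_ok <= best$value + 1e-6 * (1 + best$value)
  structure(list(s = best$par[1L], p = best$par[2L], converged = conv,
                 rss = best$value),
            class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("<sigmoid_params> s = %.4g, p = %.4g (rss %.4g%s)\n",
              x$s, x$p, x$rss, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# Shared-shape objective: total RSS over experiments for a candidate shape,
# profiling out each experiment's position parameter.
shared_shape_rss <- function(log_s, experiments) {
  s <- exp(log_s)
  sum(vapply(experiments, function(e)
    fit_sigmoid(e$dprime, e$viability, shape = s)$rss, numeric(1L)))
}

fit_shared_shape <- function(experiments) {
  opt <- stats::optimize(shared_shape_rss, interval = log(c(1e-3, 10)),
                         experiments = experiments, tol = 1e-6)
  exp(opt$minimum)
}

#' Bootstrap uncertainty for sigmoid IC50 estimates
#'
#' The screening-scale sigmoid model couples cell lines through a shared shape
#' parameter per drug; repeatedly refitting that shared parameter on random
#' 80\% subsets of the cell lines (without replacement, 100 iterations)
#' propagates between-cell-line variability into each cell line's position
#' estimate. For each cell line the SD of log10(IC50) is taken across the
#' iterations in which it was sampled.
#'
#' @param experiments list of [dose_response_experiment()]s for one drug
#'   (at least 10).
#' @param fraction subset fraction per iteration.
#' @param iterations bootstrap iterations.
#' @param seed RNG seed.
#' @param min_sampled iterations a cell line must appear in for its SD to be
#'   considered reliable.
#' @return data.frame with \code{cell_line_id}, \code{ic50_sd} (SD of
#'   log10(IC50), micromolar scale), \code{n_sampled}, \code{reliable}.
#' @export
bootstrap_ic50_sd <- function(experiments, fraction = 0.8, iterations = 100L,
                              seed = 1L, min_sampled = 5L) {
  m <- length(experiments)
  if (m < 10L)
    stop_gpdrc("gpdrc_value_error", "bootstrap needs at least 10 experiments for the drug")
  ids <- vapply(experiments, function(e) e$cell_line_id, character(1L))
  if (anyDuplicated(ids))
    stop_gpdrc("gpdrc_value_error", "experiments must come from distinct cell lines")
  k <- max(2L, floor(fraction * m))
  draws <- matrix(NA_real_, nrow = iterations, ncol = m,
                  dimnames = list(NULL, ids))
  set.seed(seed)
  for (it in seq_len(iterations)) {
    idx <- sort(sample.int(m, k, replace = FALSE))
    s_hat <- fit_shared_shape(experiments[idx])
    for (j in idx) {
      fit <- fit_sigmoid(experiments[[j]]$dprime, experiments[[j]]$viability,
                         shape = s_hat)
      draws[it, j] <- dprime_to_log10uM(fit$p, experiments[[j]]$max_log2_dose)
    }
  }
  n_sampled <- colSums(!is.na(draws))
  sds <- apply(draws, 2L, stats::sd, na.rm = TRUE)
  data.frame(cell_line_id = ids, ic50_sd = unname(sds),
             n_sampled = unname(n_sampled),
             reliable = unname(n_sampled >= min_sampled),
             stringsAsFactors = FALSE)
}
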