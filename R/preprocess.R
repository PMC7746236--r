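#' Normalize raw well intensities to relative cell viability
#'
#' Treated-well intensities are scaled against the blank (no cells) and
#' negative-control (cells, no drug) wells of the same plate group:
#' \code{V = (R - B) / (C - B)}. Values below zero, which arise when a treated
#' well reads below the blanks, are set to 0. Values above 1 (growth beyond
#' control) are retained; they are only clipped later, inside the Beta
#' likelihood, whose support is the open unit interval.
#'
#' @param R numeric vector of treated-well intensities.
#' @param B mean blank-well intensity (scalar).
#' @param C mean negative-control intensity (scalar); must exceed \code{B}.
#' @return numeric vector of relative viabilities, same length as \code{R}.
#' @examples
#' normalize_viability(c(9e4, 5e4, 2e3), B = 1e3, C = 1e5)
#' @export
normalize_viability <- function(R, B, C) {
  if (!is.numeric(R) || !all(is.finite(R)))
    stop_gpdrc("gpdrc_value_error", "treated intensities must be finite numerics")
  if (!is.finite(B) || !is.finite(C) || C <= B)
    stop_gpdrc("gpdrc_degenerate_plate_error", sprintf(
      "control mean (%.4g) must exceed blank mean (%.4g): unusable plate controls", C, B))
  V <- (R - B) / (C - B)
  V[V < 0] <- 0
  V
}

#' Rescale dosages for curve fitting
#'
#' Doses are log2-transformed and mapped to \code{d' = (d + 1) / (max(d) + 1)}
#' so that the maximum tested dose is always at \code{d' = 1}. This keeps a
#' single kernel length-scale usable across assays with different maximum
#' concentrations.
#'
#' @param doses_uM positive, non-decreasing dose concentrations in micromolar.
#' @return numeric vector of rescaled doses with attribute
#'   \code{"max_log2_dose"} (the \code{max(log2(dose))} needed to invert the
#'   transform, see [dprime_to_log10uM()]).
#' @examples
#' rescale_doses(2^c(1, 3, 7))  # 0.25 0.50 1.00
#' @export
rescale_doses <- function(doses_uM) {
  if (!is.numeric(doses_uM) || length(doses_uM) < 1L || !all(is.finite(doses_uM)) ||
      any(doses_uM <= 0))
    stop_gpdrc("gpdrc_value_error", "doses must be finite positive numbers")
  if (is.unsorted(doses_uM))
    stop_gpdrc("gpdrc_value_error", "doses must be non-decreasing")
  d <- log2(doses_uM)
  denom <- max(d) + 1
  if (abs(denom) < 1e-12)
    stop_gpdrc("gpdrc_value_error",
               "max(log2 dose) = -1: dose rescaling is undefined (division by zero)")
  if (denom < 0)
    stop_gpdrc("gpdrc_value_error",
               "max(log2 dose) < -1: rescaling would reverse dose order")
  dprime <- (d + 1) / denom
  attr(dprime, "max_log2_dose") <- max(d)
  dprime
}

#' Back-transform rescaled doses to the log10 micromolar scale
#'
#' Exact inverse of [rescale_doses()] composed with the log2-to-log10 change of
#' base: \code{d = d' * (max_d + 1) - 1}, returned as \code{d * log10(2)}.
#' Values of \code{d'} beyond 1 correspond to extrapolation past the maximum
#' tested concentration.
#'
#' @param d_prime rescaled dose value(s).
#' @param max_log2_dose the \code{max(log2(dose))} used when rescaling.
#' @return log10 concentration(s) in micromolar.
#' @export
dprime_to_log10uM <- function(d_prime, max_log2_dose) {
  (d_prime * (max_log2_dose + 1) - 1) * log10(2)
}

#' Raw-data quality-control statistic
#'
#' Spearman rank correlation between viability and dose. Well-behaved
#' experiments show viability decreasing with dose (negative rho); a positive
#' rho flags a suspect readout. Ties receive average ranks. A constant
#' viability vector returns 0 with attribute \code{degenerate = TRUE} so QC
#' tables stay numeric.
#'
#' @param experiment a [dose_response_experiment()], or a numeric dose vector
#'   when \code{viability} is supplied separately.
#' @param viability optional viability vector aligned to the doses.
#' @return Spearman rho in \[-1, 1\].
#' @export
qc_spearman <- function(experiment, viability = NULL) {
  if (is.null(viability)) {
    doses <- experiment$doses_uM
    viability <- experiment$viability
  } else {
    doses <- experiment
  }
  if (length(doses) < 3L)
    stop_gpdrc("gpdrc_value_error", "qc_spearman needs at least 3 dose points")
  if (stats::sd(viability) == 0) {
    rho <- 0
    attr(rho, "degenerate") <- TRUE
    return(rho)
  }
  stats::cor(rank(doses), rank(viability), method = "pearson")
}

#' Construct a single dose-response experiment
#'
#' Container for one drug x cell-line assay after normalisation: doses, the
#' rescaled dose axis used by all curve-fitting code, and relative viabilities.
#' Duplicate doses are allowed (e.g. technical replicate wells); doses must be
#' sorted.
#'
#' @param cell_line_id,drug_id,batch_id identifier strings.
#' @param doses_uM positive non-decreasing doses in micromolar.
#' @param viability finite relative viabilities aligned to the doses.
#' @return an object of class \code{"dose_response_experiment"} with fields
#'   \code{doses_uM}, \code{viability}, \code{dprime}, \code{max_log2_dose},
#'   \code{n}.
#' @export
dose_response_experiment <- function(cell_line_id, drug_id, batch_id = "",
                                     doses_uM, viability) {
  if (length(doses_uM) != length(viability))
    stop_gpdrc("gpdrc_value_error", "doses and viability must have equal length")
  if (!all(is.finite(viability)) || any(viability < 0))
    stop_gpdrc("gpdrc_value_error", "viability must be finite and non-negative")
  dprime <- rescale_doses(doses_uM)
  structure(list(
    cell_line_id = as.character(cell_line_id),
    drug_id = as.character(drug_id),
    batch_id = as.character(batch_id),
    doses_uM = as.numeric(doses_uM),
    viability = as.numeric(viability),
    dprime = as.numeric(dprime),
    max_log2_dose = attr(dprime, "max_log2_dose"),
    n = length(doses_uM)
  ), class = "dose_response_experiment")
}

#' @export
print.dose_response_experiment <- function(x, ...) {
  cat(sprintf("<dose_response_experiment> %s x %s (batch %s), %d doses [%.3g, %.3g] uM\n",
              x$cell_line_id, x$drug_id, x$batch_id, x$n,
              min(x$doses_uM), max(x$doses_uM)))
  invisible(x)
}

#' Assemble experiments from a raw screen table
#'
#' Groups treated wells by (cell line, drug, batch), normalises their
#' intensities against the blank and negative-control wells of the same
#' (cell line, batch) plate group, and returns one
#' [dose_response_experiment()] per group, wells sorted by dose.
#'
#' @param raw a validated raw screen table from [read_raw_screen()].
#' @return list of \code{dose_response_experiment} objects.
#' @export
screen_experiments <- function(raw) {
  treated <- raw[raw$well_type == "treated", , drop = FALSE]
  if (nrow(treated) == 0L) return(list())
  key <- interaction(treated$cell_line_id, treated$drug_id, treated$batch_id,
                     drop = TRUE, sep = "\r")
  lapply(split(treated, key), function(grp) {
    plate <- raw$cell_line_id == grp$cell_line_id[1L] & raw$batch_id == grp$batch_id[1L]
    B <- mean(raw$intensity[plate & raw$well_type == "blank"])
    C <- mean(raw$intensity[plate & raw$well_type == "neg_control"])
    ord <- order(grp$dose_uM)
    V <- normalize_viability(grp$intensity[ord], B, C)
    dose_response_experiment(grp$cell_line_id[1L], grp$drug_id[1L],
                             grp$batch_id[1L], grp$dose_uM[ord], V)
  })
}
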