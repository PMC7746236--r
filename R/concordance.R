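# Concordance between two curve-fitting methods' IC50 estimates.

#' Weighted Pearson correlation across cancer-type groups
#'
#' Computes the Pearson correlation of the two IC50 columns within each group
#' (cancer type), Fisher-z transforms, averages with weights \code{n_i - 1}
#' (group precision grows with size) and back-transforms:
#' \code{p_w = tanh(sum(w_i atanh(p_i)) / sum(w_i))}. Groups smaller than
#' \code{min_n} are excluded. Correlations of exactly +/-1 are clamped to
#' \code{1 - 1e-12} in magnitude (with a warning) before the z-transform.
#' An \code{"inverse_n"} weighting mode (\code{w_i = 1/n_i}) is provided for
#' sensitivity analysis.
#'
#' @param a,b paired IC50 vectors (e.g. GP and sigmoid log10 values).
#' @param group grouping labels (cancer type per pair).
#' @param min_n minimum group size.
#' @param weights \code{"n_minus_1"} (default) or \code{"inverse_n"}.
#' @return object of class \code{"weighted_pearson"}: \code{p_w} plus the
#'   per-group correlations and sizes.
#' @export
weighted_pearson <- function(a, b, group, min_n = 10L,
                             weights = c("n_minus_1", "inverse_n")) {
  weights <- match.arg(weights)
  stopifnot(length(a) == length(b), length(a) == length(group))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]; group <- group[keep]
  sizes <- table(group)
  groups <- names(sizes)[sizes >= min_n]
  if (!length(groups))
    stop_gpdrc("gpdrc_value_error",
               sprintf("no group with at least %d pairs", min_n))
  p_i <- vapply(groups, function(gname) {
    sel <- group == gname
    stats::cor(a[sel], b[sel])
  }, numeric(1L))
  n_i <- as.integer(sizes[groups])
  if (any(abs(p_i) >= 1 - 1e-12)) {
    warning("group correlation at +/-1 clamped before Fisher z-transform")
    p_i <- pmin(pmax(p_i, -(1 - 1e-12)), 1 - 1e-12)
  }
  w_i <- if (weights == "n_minus_1") n_i - 1 else 1 / n_i
  p_w <- tanh(sum(w_i * atanh(p_i)) / sum(w_i))
  structure(list(p_w = p_w, p_i = unname(p_i), n_i = n_i,
                 groups = groups, weights = weights),
            class = "weighted_pearson")
}

#' @export
print.weighted_pearson <- function(x, ...) {
  cat(sprintf("<weighted_pearson> p_w = %.4f over %d group(s) (n = %s)\n",
              x$p_w, length(x$groups), paste(x$n_i, collapse = ", ")))
  invisible(x)
}

#' Per-experiment IC50 differences between two response tables
#'
#' Matches the tables on (cell line, drug) and reports
#' \code{df = IC50_a - IC50_b} on the log10 micromolar scale, stratified by
#' whether the first table's estimate lies within or beyond the maximum
#' tested concentration. Unmatched rows are reported and excluded.
#'
#' @param gp_table,sigmoid_table response tables (conventionally GP first, so
#'   positive differences mean the GP calls a higher IC50).
#' @return data.frame with \code{cell_line_id}, \code{drug_id}, \code{df},
#'   \code{within_range}; attributes \code{n_unmatched} and \code{summary}
#'   (mean df per stratum).
#' @export
ic50_difference <- function(gp_table, sigmoid_table) {
  key_a <- paste(gp_table$cell_line_id, gp_table$drug_id, sep = "\r")
  key_b <- paste(sigmoid_table$cell_line_id, sigmoid_table$drug_id, sep = "\r")
  common <- intersect(key_a, key_b)
  n_unmatched <- (length(key_a) - length(common)) +
    (length(key_b) - length(common))
  if (n_unmatched)
    warning(sprintf("%d unmatched row(s) excluded", n_unmatched))
  ia <- match(common, key_a); ib <- match(common, key_b)
  out <- data.frame(
    cell_line_id = gp_table$cell_line_id[ia],
    drug_id = gp_table$drug_id[ia],
    df = gp_table$ic50_mean_log10uM[ia] - sigmoid_table$ic50_mean_log10uM[ib],
    within_range = gp_table$within_range[ia],
    stringsAsFactors = FALSE)
  ok <- is.finite(out$df)
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "summary") <- c(
    mean_df_within = mean(out$df[ok & out$within_range]),
    mean_df_beyond = mean(out$df[ok & !out$within_range]))
  out
}
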