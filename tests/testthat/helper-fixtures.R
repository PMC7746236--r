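# Shared fixtures, all generated in code.

# Minimal raw screen CSV: 4 treated wells + 1 blank + 1 control on one plate.
write_toy_raw_csv <- function(path) {
  writeLines(c(
    "cell_line_id,drug_id,batch_id,well_type,dose_uM,intensity",
    "CL1,D1,B1,treated,0.625,90000",
    "CL1,D1,B1,treated,2.5,60000",
    "CL1,D1,B1,treated,10,20000",
    "CL1,D1,B1,treated,40,5000",
    "CL1,-,B1,blank,,1000",
    "CL1,-,B1,neg_control,,100000"
  ), path)
  path
}

# Noise-free experiment from an exact sigmoid truth.
exact_sigmoid_experiment <- function(s = 0.2, p = 0.6, n = 9L, fold = 2,
                                     top_dose_uM = 10) {
  doses <- top_dose_uM / fold^((n - 1L):0L)
  dprime <- as.numeric(rescale_doses(doses))
  dose_response_experiment("CL1", "D1", "B1", doses,
                           sigmoid_curve(dprime, s, p))
}

# Dense 2-D grid integration of the exact 2-point posterior over the latent f;
# independent oracle for the variational fit.
grid_posterior_2pt <- function(experiment, posterior, half_width = 8,
                               grid_n = 701L) {
  lik <- posterior$likelihood_params
  yc <- pmin(pmax(experiment$viability, lik$eps), 1 - lik$eps)
  gr <- seq(-half_width, half_width, length.out = grid_n)
  G <- as.matrix(expand.grid(f1 = gr, f2 = gr))
  Ki <- solve(posterior$K + diag(posterior$jitter, 2L))
  lp <- -0.5 * rowSums(((G - posterior$prior_mean) %*% Ki) *
                         (G - posterior$prior_mean)) +
    mixture_loglik(yc[1L], G[, 1L], lik) + mixture_loglik(yc[2L], G[, 2L], lik)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_exact <- colSums(w * G)
  var_exact <- colSums(w * (G - rep(1, nrow(G)) %o% mean_exact)^2)
  list(mean = mean_exact, var = var_exact)
}

rel_norm_err <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
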