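# Biomarker association tests.
#
# Frequentist: ANOVA as the linear model g_i = alpha + beta z_i + gamma x_i + e_i
# (z_i = 0/1 feature status, x_i = tissue covariates), F-test on beta.
#
# Bayesian: the same linear predictor, but each cell line's response mean
# carries its own estimation SD sigma_i from the curve fit. Collapsing the
# hierarchy gives g_i ~ N(alpha + beta z_i + gamma x_i, (sigma_i^c)^2 + sigma*^2)
# with priors beta ~ N(0, 0.1), sigma*^2 ~ Exp(10), alpha ~ N(0, tau^2),
# tau ~ Gamma(1, 1). The exponent c in [0,1] attenuates the influence of the
# per-cell-line uncertainties (c = 0 ignores them). Sampled by Hamiltonian
# Monte Carlo on (alpha, beta, gamma, log sigma*^2, log tau).

#' Configuration for the Bayesian hierarchical biomarker test
#'
#' @param beta_prior_sd prior SD of the effect size (the N(0, 0.1) effect
#'   prior read as variance 0.1).
#' @param sigma_star_sq_exp_rate rate of the exponential prior on the
#'   between-cell-line variance.
#' @param tau_gamma_shape,tau_gamma_rate Gamma prior on the global-mean scale.
#' @param c uncertainty exponent in \[0, 1\]; estimation SDs enter as
#'   \code{sigma_i^c} (with \code{0^c = 0}).
#' @param chains,warmup,draws HMC chains and per-chain iterations.
#' @param leapfrog base number of leapfrog steps (jittered per iteration).
#' @param target_accept dual-averaging target acceptance rate.
#' @param rhat_threshold convergence-diagnostic threshold.
#' @param max_divergence_rate divergence share above which the result is
#'   flagged unreliable.
#' @param seed RNG seed.
#' @return list of class \code{"bayes_test_config"}.
#' @export
bayes_test_config <- function(beta_prior_sd = sqrt(0.1),
                              sigma_star_sq_exp_rate = 10,
                              tau_gamma_shape = 1, tau_gamma_rate = 1,
                              c = 0.25, chains = 4L, warmup = 1000L,
                              draws = 1000L, leapfrog = 15L,
                              target_accept = 0.8, rhat_threshold = 1.01,
                              max_divergence_rate = 0.02, seed = 1L) {
  stopifnot(c >= 0, c <= 1, beta_prior_sd > 0, sigma_star_sq_exp_rate > 0,
            tau_gamma_shape > 0, tau_gamma_rate > 0)
  structure(list(beta_prior_sd = beta_prior_sd,
                 sigma_star_sq_exp_rate = sigma_star_sq_exp_rate,
                 tau_gamma_shape = tau_gamma_shape,
                 tau_gamma_rate = tau_gamma_rate, c = c,
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), leapfrog = as.integer(leapfrog),
                 target_accept = target_accept,
                 rhat_threshold = rhat_threshold,
                 max_divergence_rate = max_divergence_rate,
                 seed = as.integer(seed)),
            class = "bayes_test_config")
}

# Build the (n x p) covariate matrix from a tissue factor (one-hot, first
# level as reference) or accept a numeric matrix as-is.
covariate_matrix <- function(x, n) {
  if (is.null(x)) return(matrix(numeric(0), nrow = n, ncol = 0L))
  if (is.numeric(x) && is.matrix(x)) return(x)
  f <- factor(x)
  if (nlevels(f) < 2L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  stats::model.matrix(~ f)[, -1L, drop = FALSE]
}

check_groups <- function(z, min_group = 3L) {
  n1 <- sum(z == 1)
  n0 <- sum(z == 0)
  if (n1 < min_group || n0 < min_group)
    stop_gpdrc("gpdrc_group_size_error", sprintf(
      "each feature group needs >= %d cell lines (mutant %d, wildtype %d)",
      min_group, n1, n0))
  c(n_mut = n1, n_wt = n0)
}

#' ANOVA biomarker association test
#'
#' OLS fit of \code{g ~ z + covariates}; the reported p-value is the partial
#' F-test on the feature indicator. Cohen's d is computed on
#' covariate-adjusted responses (residuals of \code{g ~ covariates}) with the
#' pooled SD. The q-value slot is NA here; [test_biomarkers()] fills it by
#' Benjamini-Hochberg across the whole test family.
#'
#' @param g per-cell-line response summaries (log10 IC50 means by default).
#' @param z 0/1 feature status.
#' @param x optional covariates: tissue labels (factor/character) or a
#'   numeric design matrix.
#' @param min_group minimum cell lines per feature group.
#' @return object of class \code{"anova_result"}.
#' @export
anova_test <- function(g, z, x = NULL, min_group = 3L) {
  stopifnot(length(g) == length(z), all(z %in% c(0, 1)))
  counts <- check_groups(z, min_group)
  X <- covariate_matrix(x, length(g))
  design <- cbind(intercept = 1, z = z, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop_gpdrc("gpdrc_rank_error", sprintf(
      "design matrix rank-deficient; collinear column(s): %s",
      paste(dropped, collapse = ", ")))
  }
  dat <- data.frame(g = g, z = z)
  if (ncol(X)) {
    dat <- cbind(dat, as.data.frame(X))
    full <- stats::lm(g ~ ., data = dat)
    reduced <- stats::lm(g ~ . - z, data = dat)
  } else {
    full <- stats::lm(g ~ z, data = dat)
    reduced <- stats::lm(g ~ 1, data = dat)
  }
  an <- stats::anova(reduced, full)
  # covariate-adjusted responses: strip gamma*x but keep the z effect
  adj <- stats::residuals(full) + stats::coef(full)[["(Intercept)"]] +
    stats::coef(full)[["z"]] * z
  r1 <- adj[z == 1]; r0 <- adj[z == 0]
  pooled <- sqrt(((length(r1) - 1) * stats::var(r1) +
                    (length(r0) - 1) * stats::var(r0)) /
                   (length(r1) + length(r0) - 2))
  structure(list(
    beta_hat = stats::coef(full)[["z"]],
    F_stat = an$F[2L],
    p_value = an$`Pr(>F)`[2L],
    q_value = NA_real_,
    cohens_d = (mean(r1) - mean(r0)) / pooled,
    n_mut = unname(counts["n_mut"]), n_wt = unname(counts["n_wt"]),
    residual_variance = stats::sigma(full)^2
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> beta = %.3f, F = %.2f, p = %.3g, d = %.2f (n_mut %d, n_wt %d)\n",
              x$beta_hat, x$F_stat, x$p_value, x$cohens_d, x$n_mut, x$n_wt))
  invisible(x)
}

#' Posterior probability of a sign change in the effect
#'
#' Estimates the posterior mode of the effect-size draws by a Gaussian kernel
#' density (Silverman's bandwidth) and returns the posterior mass on the
#' opposite side of zero: \code{P(beta < 0)} when the mode is positive,
#' \code{P(beta > 0)} when negative. Exactly symmetric draws give 0.5.
#'
#' @param beta_samples at least 100 posterior draws of the effect size.
#' @return probability in \[0, 0.5\] (up to Monte-Carlo noise).
#' @export
sign_change_probability <- function(beta_samples) {
  if (length(beta_samples) < 100L)
    stop_gpdrc("gpdrc_value_error", "need at least 100 posterior draws")
  mode <- posterior_mode(beta_samples)
  if (mode > 0) mean(beta_samples < 0) else mean(beta_samples > 0)
}

posterior_mode <- function(samples) {
  if (stats::sd(samples) == 0) return(samples[1L])
  dens <- stats::density(samples, bw = "nrd0")
  dens$x[which.max(dens$y)]
}

# --- collapsed-model log posterior and gradient -----------------------------
# theta = (alpha, beta, gamma[p], u = log sigma*^2, w = log tau)
make_bayes_lp <- function(g, z, X, s2c, cfg) {
  p <- ncol(X)
  n <- length(g)
  lp <- function(th) {
    alpha <- th[1L]; beta <- th[2L]
    gamma <- if (p) th[2L + seq_len(p)] else numeric(0)
    u <- th[3L + p]; w <- th[4L + p]
    s2 <- exp(u); tau <- exp(w)
    mu <- alpha + beta * z + if (p) as.vector(X %*% gamma) else 0
    v <- s2c + s2
    sum(-0.5 * log(2 * pi * v) - 0.5 * (g - mu)^2 / v) +
      stats::dnorm(beta, 0, cfg$beta_prior_sd, log = TRUE) +
      (if (p) sum(stats::dnorm(gamma, 0, 1, log = TRUE)) else 0) +
      stats::dnorm(alpha, 0, tau, log = TRUE) +
      stats::dgamma(tau, cfg$tau_gamma_shape, cfg$tau_gamma_rate, log = TRUE) + w +
      log(cfg$sigma_star_sq_exp_rate) - cfg$sigma_star_sq_exp_rate * s2 + u
  }
  grad <- function(th) {
    alpha <- th[1L]; beta <- th[2L]
    gamma <- if (p) th[2L + seq_len(p)] else numeric(0)
    u <- th[3L + p]; w <- th[4L + p]
    s2 <- exp(u); tau <- exp(w)
    mu <- alpha + beta * z + if (p) as.vector(X %*% gamma) else 0
    v <- s2c + s2
    r <- (g - mu) / v
    g_alpha <- sum(r) - alpha / tau^2
    g_beta <- sum(r * z) - beta / cfg$beta_prior_sd^2
    g_gamma <- if (p) as.vector(crossprod(X, r)) - gamma else numeric(0)
    g_u <- sum(-0.5 / v + 0.5 * (g - mu)^2 / v^2) * s2 -
      cfg$sigma_star_sq_exp_rate * s2 + 1
    g_w <- -1 + alpha^2 / tau^2 +
      (cfg$tau_gamma_shape - 1) - cfg$tau_gamma_rate * tau + 1
    c(g_alpha, g_beta, g_gamma, g_u, g_w)
  }
  list(lp = lp, grad = grad, p = p)
}

# One HMC chain with dual-averaging step-size adaptation during warmup and a
# diagonal mass matrix re-estimated halfway through warmup.
hmc_chain <- function(lp, grad, init, warmup, draws, L0, target, seed) {
  set.seed(seed)
  d <- length(init)
  th <- init
  cur_lp <- lp(th)
  eps <- 0.1; mu_da <- log(10 * eps); log_eps_bar <- log(eps)
  H_bar <- 0; gam <- 0.05; t0 <- 10; kap <- 0.75
  mass <- rep(1, d)
  keep <- matrix(NA_real_, nrow = draws, ncol = d)
  warm_hist <- matrix(NA_real_, nrow = warmup, ncol = d)
  divergences <- 0L
  total <- warmup + draws
  for (it in seq_len(total)) {
    L <- sample(max(2L, round(0.8 * L0)):round(1.2 * L0), 1L)
    r0 <- stats::rnorm(d, 0, sqrt(mass))
    th_p <- th; r <- r0
    gr <- grad(th_p)
    diverged <- FALSE
    for (l in seq_len(L)) {
      r <- r + 0.5 * eps * gr
      th_p <- th_p + eps * r / mass
      gr <- tryCatch(grad(th_p), error = function(e) rep(NaN, d))
      if (any(!is.finite(gr))) { diverged <- TRUE; break }
      r <- r + 0.5 * eps * gr
    }
    prop_lp <- if (diverged) -Inf else tryCatch(lp(th_p), error = function(e) -Inf)
    dH <- (prop_lp - 0.5 * sum(r^2 / mass)) - (cur_lp - 0.5 * sum(r0^2 / mass))
    if (!is.finite(dH) || dH < -1000) { diverged <- TRUE; dH <- -Inf }
    a_prob <- min(1, exp(dH))
    if (diverged && it > warmup) divergences <- divergences + 1L
    if (stats::runif(1L) < a_prob) { th <- th_p; cur_lp <- prop_lp }
    if (it <= warmup) {
      # dual averaging (Hoffman & Gelman)
      H_bar <- (1 - 1 / (it + t0)) * H_bar + (target - a_prob) / (it + t0)
      log_eps <- mu_da - sqrt(it) / gam * H_bar
      eta <- it^(-kap)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      eps <- exp(log_eps)
      warm_hist[it, ] <- th
      if (it == floor(warmup / 2) && it >= 20L) {
        seg <- warm_hist[floor(it / 2):it, , drop = FALSE]
        mass <- 1 / pmax(apply(seg, 2L, stats::var), 1e-6)
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      keep[it - warmup, ] <- th
    }
  }
  list(draws = keep, divergences = divergences, step_size = eps)
}

split_rhat <- function(chains_list) {
  # split-R-hat per parameter over a list of draws matrices
  halves <- list()
  for (ch in chains_list) {
    m <- nrow(ch) %/% 2L
    halves <- c(halves, list(ch[seq_len(m), , drop = FALSE]),
                list(ch[(m + 1L):(2L * m), , drop = FALSE]))
  }
  m <- length(halves); nn <- nrow(halves[[1L]])
  vapply(seq_len(ncol(halves[[1L]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1L))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1L))
    W <- mean(vars); B <- nn * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }, numeric(1L))
}

#' Hierarchical Bayesian biomarker test with uncertainty propagation
#'
#' Samples the collapsed hierarchical model (see the header of this file) by
#' Hamiltonian Monte Carlo and summarises the effect-size posterior. Cell
#' lines whose response estimate carries a large estimation SD contribute a
#' larger likelihood variance and are therefore down-weighted — the mechanism
#' by which uncertain measurements are prevented from driving associations.
#'
#' @param g per-cell-line response summaries (log10 IC50 means).
#' @param z 0/1 feature status.
#' @param sigma per-cell-line estimation SDs (zeros allowed).
#' @param x optional covariates as in [anova_test()].
#' @param config a [bayes_test_config()].
#' @param min_group minimum cell lines per feature group.
#' @return object of class \code{"bayes_test_result"} with posterior
#'   summaries for beta (mode, mean, 90\% CI, draws), alpha, gamma,
#'   sigma_star, the sign-change probability, and diagnostics (split R-hat,
#'   divergence count, reliability flag).
#' @export
bayes_hierarchical_test <- function(g, z, sigma, x = NULL,
                                    config = bayes_test_config(),
                                    min_group = 3L) {
  stopifnot(length(g) == length(z), length(sigma) == length(g),
            all(z %in% c(0, 1)), all(sigma >= 0))
  check_groups(z, min_group)
  X <- covariate_matrix(x, length(g))
  s_c <- ifelse(sigma == 0, 0, sigma^config$c)  # 0^c := 0, including c = 0
  model <- make_bayes_lp(g, z, X, s_c^2, config)
  p <- model$p
  d <- 4L + p

  chains <- vector("list", config$chains)
  divergences <- 0L
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 1000L * ch)
    init <- c(mean(g) + stats::rnorm(1, 0, 0.1), stats::rnorm(1, 0, 0.1),
              stats::rnorm(p, 0, 0.1),
              log(max(stats::var(g) / 2, 1e-3)) + stats::rnorm(1, 0, 0.1),
              stats::rnorm(1, 0, 0.1))
    res <- hmc_chain(model$lp, model$grad, init, config$warmup, config$draws,
                     config$leapfrog, config$target_accept,
                     seed = config$seed + 7919L * ch)
    chains[[ch]] <- res$draws
    divergences <- divergences + res$divergences
  }
  all_draws <- do.call(rbind, chains)
  beta <- all_draws[, 2L]
  rhat <- if (config$chains > 1L || config$draws >= 4L) split_rhat(chains)
          else rep(NA_real_, d)
  div_rate <- divergences / (config$chains * config$draws)
  reliable <- div_rate <= config$max_divergence_rate &&
    (all(is.na(rhat)) || max(rhat) <= config$rhat_threshold)

  sigma_star <- sqrt(exp(all_draws[, 3L + p]))
  gamma_summary <- if (p)
    list(mean = colMeans(all_draws[, 2L + seq_len(p), drop = FALSE]),
         sd = apply(all_draws[, 2L + seq_len(p), drop = FALSE], 2L, stats::sd))
  else NULL
  structure(list(
    beta_mode = posterior_mode(beta),
    beta_mean = mean(beta),
    beta_ci90 = unname(stats::quantile(beta, c(0.05, 0.95))),
    beta_samples = beta,
    alpha = list(mean = mean(all_draws[, 1L]), sd = stats::sd(all_draws[, 1L])),
    gamma = gamma_summary,
    sigma_star = list(mean = mean(sigma_star), sd = stats::sd(sigma_star)),
    sign_change_prob = sign_change_probability(beta),
    diagnostics = list(rhat = rhat, max_rhat = max(rhat),
                       divergences = divergences,
                       divergence_rate = div_rate, reliable = reliable)
  ), class = "bayes_test_result")
}

#' @export
print.bayes_test_result <- function(x, ...) {
  cat(sprintf(
    "<bayes_test_result> beta mode = %.3f, mean = %.3f, 90%% CI [%.3f, %.3f]\n  sign-change prob = %.4f, sigma* = %.3f, max R-hat = %.3f%s\n",
    x$beta_mode, x$beta_mean, x$beta_ci90[1L], x$beta_ci90[2L],
    x$sign_change_prob, x$sigma_star$mean, x$diagnostics$max_rhat,
    if (x$diagnostics$reliable) "" else " (UNRELIABLE)"))
  invisible(x)
}

#' Run biomarker tests across a response table and a binary event matrix
#'
#' Joins responses and features on cell line, runs the requested test(s) per
#' (drug, feature) — within each cancer type when \code{by_cancer_type} is
#' TRUE (no tissue covariate then), across all cell lines with a tissue
#' one-hot covariate otherwise — and Benjamini-Hochberg-adjusts the ANOVA
#' p-values across the whole family. Combinations with too-small groups or
#' rank-deficient designs are recorded with a skip reason.
#'
#' @param responses response table (rows with the chosen \code{method}).
#' @param bem a [read_bem()] result.
#' @param method \code{"anova"}, \code{"bayes"} or \code{"both"}.
#' @param by_cancer_type test within each cancer type separately.
#' @param config a [bayes_test_config()].
#' @param min_group minimal per-group cell-line count.
#' @return data.frame: one row per (drug, feature, cancer type) with ANOVA
#'   and/or Bayesian statistics, q-values, and a diagnostics/skip flag.
#' @export
test_biomarkers <- function(responses, bem, method = c("both", "anova", "bayes"),
                            by_cancer_type = FALSE,
                            config = bayes_test_config(), min_group = 3L) {
  method <- match.arg(method)
  do_anova <- method %in% c("anova", "both")
  do_bayes <- method %in% c("bayes", "both")
  rows <- list()
  types <- if (by_cancer_type) unique(bem$cancer_type) else NA_character_
  for (drug in unique(responses$drug_id)) {
    rtab <- responses[responses$drug_id == drug, ]
    for (type in types) {
      keep_ids <- if (is.na(type)) bem$cell_line_ids
                  else bem$cell_line_ids[bem$cancer_type == type]
      idx <- match(intersect(rtab$cell_line_id, keep_ids), rtab$cell_line_id)
      sub <- rtab[idx, ]
      sub <- sub[is.finite(sub$ic50_mean_log10uM), ]
      if (nrow(sub) < 2L * min_group) next
      bem_idx <- match(sub$cell_line_id, bem$cell_line_ids)
      xcov <- if (is.na(type) && length(unique(bem$cancer_type[bem_idx])) > 1L)
        bem$cancer_type[bem_idx] else NULL
      sig <- sub$ic50_sd
      sig[!is.finite(sig)] <- 0
      for (feat in bem$feature_ids) {
        z <- bem$values[bem_idx, feat]
        row <- data.frame(drug_id = drug, feature_id = feat,
                          cancer_type = ifelse(is.na(type), "all", type),
                          n_mut = sum(z == 1), n_wt = sum(z == 0),
                          anova_beta = NA_real_, cohens_d = NA_real_,
                          p = NA_real_, q = NA_real_,
                          bayes_beta_mode = NA_real_,
                          sign_change_prob = NA_real_,
                          flag = "ok", stringsAsFactors = FALSE)
        out <- tryCatch({
          if (do_anova) {
            a <- anova_test(sub$ic50_mean_log10uM, z, xcov, min_group)
            row$anova_beta <- a$beta_hat; row$cohens_d <- a$cohens_d
            row$p <- a$p_value
          }
          if (do_bayes) {
            b <- bayes_hierarchical_test(sub$ic50_mean_log10uM, z, sig, xcov,
                                         config, min_group)
            row$bayes_beta_mode <- b$beta_mode
            row$sign_change_prob <- b$sign_change_prob
            if (!b$diagnostics$reliable) row$flag <- "unreliable_mcmc"
          }
          row
        }, gpdrc_error = function(e) { row$flag <- conditionMessage(e); row })
        rows[[length(rows) + 1L]] <- out
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab) && any(!is.na(tab$p)))
    tab$q[!is.na(tab$p)] <- stats::p.adjust(tab$p[!is.na(tab$p)], method = "BH")
  tab
}
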