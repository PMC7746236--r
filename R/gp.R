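# Gaussian process dose-response model.
#
# Latent curve f has a GP prior with a linear + Matern-3/2 kernel on the
# rescaled dose axis; observed viabilities follow a two-component Beta
# mixture: component 1 (weight pi_mix) is the drug response with mean
# Phi(f) (probit link into (0,1)) and scale s1, component 2 captures rare
# high-viability outliers with fixed mean mu2 and scale s2. Inference is
# variational: q(f) = N(m_q, S) with the natural structure
# S = (K^-1 + diag(lambda))^-1, optimised by L-BFGS-B with analytic ELBO
# gradients; the non-conjugate expectation uses Gauss-Hermite quadrature.

#' Parameters of the two-component Beta-mixture likelihood
#'
#' Defaults follow the screening calibration: response-component scale
#' \code{s1 = 50}, outlier scale \code{s2 = 11}, outlier mean viability
#' \code{mu2 = 0.9} (outliers are mostly erroneous resistance readings) and
#' mixture weight \code{pi_mix = 0.999} (outliers are rare).
#'
#' @param s1,s2 Beta scale parameters of response and outlier components.
#' @param mu2 outlier-component mean viability in (0,1).
#' @param pi_mix response-component weight in (0,1].
#' @param eps clipping margin applied to viabilities before likelihood
#'   evaluation (Beta support is the open unit interval).
#' @return list of class \code{"mixture_likelihood_params"}.
#' @export
mixture_likelihood_params <- function(s1 = 50, s2 = 11, mu2 = 0.9,
                                      pi_mix = 0.999, eps = 1e-3) {
  stopifnot(s1 > 0, s2 > 0, mu2 > 0, mu2 < 1, pi_mix > 0, pi_mix <= 1,
            eps > 0, eps < 0.5)
  structure(list(s1 = s1, s2 = s2, mu2 = mu2, pi_mix = pi_mix, eps = eps),
            class = "mixture_likelihood_params")
}

#' Kernel configuration for the dose-response GP
#'
#' Combined linear + Matern-3/2 covariance on rescaled doses:
#' \code{K = lin_var * x x' + mat_var * (1 + sqrt(3) r / l) exp(-sqrt(3) r / l)}.
#' Defaults are the fixed empirical values used throughout: Matern variance
#' 0.2, length-scale 0.3, linear variance 0.1. The prior mean is constant;
#' by default it is set per experiment to the probit of the mean observed
#' viability.
#'
#' @param matern_variance,matern_lengthscale,linear_variance positive reals.
#' @param prior_mean_mode \code{"empirical_probit"} or \code{"fixed"}.
#' @param prior_mean_value constant latent prior mean used when
#'   \code{prior_mean_mode = "fixed"}.
#' @return list of class \code{"gp_kernel_config"}.
#' @export
gp_kernel_config <- function(matern_variance = 0.2, matern_lengthscale = 0.3,
                             linear_variance = 0.1,
                             prior_mean_mode = c("empirical_probit", "fixed"),
                             prior_mean_value = 0) {
  stopifnot(matern_variance > 0, matern_lengthscale > 0, linear_variance > 0)
  structure(list(matern_variance = matern_variance,
                 matern_lengthscale = matern_lengthscale,
                 linear_variance = linear_variance,
                 prior_mean_mode = match.arg(prior_mean_mode),
                 prior_mean_value = prior_mean_value),
            class = "gp_kernel_config")
}

#' Variational-inference settings
#'
#' @param max_iter L-BFGS-B iteration cap.
#' @param reltol relative ELBO tolerance.
#' @param quad_points Gauss-Hermite nodes for the likelihood expectation.
#' @param jitter_ladder increasing jitters tried when factorising kernels.
#' @return list of class \code{"vi_config"}.
#' @export
vi_config <- function(max_iter = 2000L, reltol = 1e-6, quad_points = 30L,
                      jitter_ladder = c(0, 1e-8, 1e-6, 1e-4)) {
  structure(list(max_iter = as.integer(max_iter), reltol = reltol,
                 quad_points = as.integer(quad_points),
                 jitter_ladder = jitter_ladder),
            class = "vi_config")
}

#' Log density of the mean-parameterised Beta distribution
#'
#' \code{Beta_mu(y | mu, s) = Beta(y; a = mu s, b = (1 - mu) s)}, so \code{mu}
#' is the mean and \code{s} a concentration/scale. \code{mu = 0.5, s = 2} is
#' the uniform distribution.
#'
#' @param y values strictly inside (0, 1).
#' @param mu mean in (0, 1).
#' @param s scale > 0.
#' @return log density, vectorised over arguments.
#' @export
beta_mu_logpdf <- function(y, mu, s) {
  if (any(y <= 0 | y >= 1))
    stop_gpdrc("gpdrc_domain_error",
               "beta_mu_logpdf requires y strictly inside (0,1); clip first")
  if (any(mu <= 0 | mu >= 1) || any(s <= 0))
    stop_gpdrc("gpdrc_domain_error", "mu must lie in (0,1) and s > 0")
  stats::dbeta(y, mu * s, (1 - mu) * s, log = TRUE)
}

clip_unit <- function(y, eps) pmin(pmax(y, eps), 1 - eps)

#' Beta-mixture log likelihood of viability given the latent function
#'
#' \code{log\[pi * Beta_mu(y | Phi(f), s1) + (1 - pi) * Beta_mu(y | mu2, s2)\]}
#' with \code{Phi} the standard normal CDF mapping the real-valued latent GP
#' into the Beta mean.
#'
#' @param y viabilities, clipped to \[eps, 1 - eps\] (see
#'   [mixture_likelihood_params()]).
#' @param f_latent latent function values (recycled against \code{y}).
#' @param params a [mixture_likelihood_params()].
#' @return log density, vectorised.
#' @export
mixture_loglik <- function(y, f_latent, params = mixture_likelihood_params()) {
  mu1 <- clip_unit(stats::pnorm(f_latent), 1e-10)
  l1 <- beta_mu_logpdf(y, mu1, params$s1)
  if (params$pi_mix == 1) return(l1)
  l2 <- beta_mu_logpdf(y, params$mu2, params$s2)
  a <- log(params$pi_mix) + l1
  b <- log1p(-params$pi_mix) + l2
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# d/df of mixture_loglik: responsibility of component 1 times the chain rule
# through the probit link and the Beta_mu mean.
mixture_loglik_df <- function(y, f_latent, params) {
  mu1 <- clip_unit(stats::pnorm(f_latent), 1e-10)
  l1 <- beta_mu_logpdf(y, mu1, params$s1)
  if (params$pi_mix == 1) {
    r1 <- 1
  } else {
    l2 <- beta_mu_logpdf(y, params$mu2, params$s2)
    a <- log(params$pi_mix) + l1
    b <- log1p(-params$pi_mix) + l2
    r1 <- 1 / (1 + exp(b - a))
  }
  dl1_dmu <- params$s1 * (log(y / (1 - y)) - digamma(mu1 * params$s1) +
                            digamma((1 - mu1) * params$s1))
  r1 * dl1_dmu * stats::dnorm(f_latent)
}

#' Covariance matrix of the linear + Matern-3/2 kernel
#'
#' @param x,x_prime rescaled dose vectors.
#' @param config a [gp_kernel_config()].
#' @return \code{length(x)} x \code{length(x_prime)} covariance matrix.
#' @examples
#' kernel_matrix(1, 1, gp_kernel_config())  # 0.1 + 0.2 = 0.3
#' @export
kernel_matrix <- function(x, x_prime, config = gp_kernel_config()) {
  r <- abs(outer(x, x_prime, "-"))
  z <- sqrt(3) * r / config$matern_lengthscale
  config$linear_variance * outer(x, x_prime) +
    config$matern_variance * (1 + z) * exp(-z)
}

# Cholesky with escalating jitter; classed error if the ladder is exhausted.
chol_jitter <- function(K, ladder = c(0, 1e-8, 1e-6, 1e-4)) {
  for (j in ladder) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  stop_gpdrc("gpdrc_numeric_error",
             "covariance matrix not positive definite after jitter escalation")
}

# ELBO and analytic gradient for q(f) = N(m_q, S), S = (K^-1 + diag(lambda))^-1,
# parameters par = c(m_q, log(lambda)). Returns the *negative* ELBO for optim.
make_elbo <- function(y, Kinv, logdetK, m0, params, gh, trace_env) {
  n <- length(y)
  w <- gh$w / sqrt(pi)
  xq <- gh$x
  ly <- log(y / (1 - y))

  eval_parts <- function(par) {
    m_q <- par[seq_len(n)]
    lam <- exp(par[n + seq_len(n)])
    A <- Kinv + diag(lam, n)
    cA <- chol(A)
    S <- chol2inv(cA)
    v <- pmax(diag(S), 1e-12)
    Fq <- m_q + sqrt(2 * v) %o% xq          # n x Q latent nodes
    LL <- matrix(mixture_loglik(rep(y, length(xq)), as.vector(Fq), params),
                 nrow = n)
    Eterm <- sum(LL %*% w)
    delta <- m_q - m0
    Kid <- Kinv %*% delta
    kl <- 0.5 * (sum(Kinv * S) + sum(delta * Kid) - n +
                   logdetK + 2 * sum(log(diag(cA))))
    list(elbo = Eterm - kl, m_q = m_q, lam = lam, S = S, v = v, Fq = Fq,
         Kid = Kid)
  }

  # Non-finite iterates can appear transiently during line search; a large
  # finite penalty makes L-BFGS-B back off instead of aborting the fit.
  fn <- function(par) {
    p <- tryCatch(eval_parts(par), error = function(e) NULL)
    if (is.null(p) || !is.finite(p$elbo)) return(1e10)
    trace_env$trace <- c(trace_env$trace, p$elbo)
    -p$elbo
  }
  gr <- function(par) {
    p <- tryCatch(eval_parts(par), error = function(e) NULL)
    if (is.null(p) || !is.finite(p$elbo)) return(numeric(2L * n))
    DL <- matrix(mixture_loglik_df(rep(y, length(xq)), as.vector(p$Fq), params),
                 nrow = n)
    g <- DL %*% w                               # dE/dm_q
    h <- (DL %*% (w * xq)) / sqrt(2 * p$v)      # dE/dv
    grad_m <- as.vector(g - p$Kid)
    S2 <- p$S^2
    grad_lam <- as.vector(-S2 %*% h - 0.5 * (S2 %*% p$lam))
    out <- -c(grad_m, grad_lam * p$lam)
    if (any(!is.finite(out))) return(numeric(2L * n))
    out
  }
  list(fn = fn, gr = gr, eval_parts = eval_parts)
}

#' Fit the GP dose-response model by variational inference
#'
#' Maximises the evidence lower bound over a Gaussian variational posterior
#' for the latent function at the observed (rescaled) doses. Kernel and
#' likelihood hyperparameters are fixed constants (not optimised per
#' experiment). The fit is deterministic; \code{seed} is accepted for
#' interface symmetry with the samplers.
#'
#' @param experiment a [dose_response_experiment()] (viabilities are clipped
#'   to the open unit interval internally).
#' @param kernel_config a [gp_kernel_config()].
#' @param likelihood_params a [mixture_likelihood_params()].
#' @param vi a [vi_config()].
#' @param seed unused RNG seed, kept for a uniform fitting interface.
#' @return object of class \code{"gp_posterior"}: train inputs, variational
#'   mean/covariance, prior pieces, configs, ELBO trace and convergence flag.
#' @export
fit_gp <- function(experiment, kernel_config = gp_kernel_config(),
                   likelihood_params = mixture_likelihood_params(),
                   vi = vi_config(), seed = NULL) {
  x <- experiment$dprime
  n <- length(x)
  if (n < 1L) stop_gpdrc("gpdrc_value_error", "experiment has no observations")
  y <- clip_unit(experiment$viability, likelihood_params$eps)

  m0v <- if (kernel_config$prior_mean_mode == "empirical_probit")
    stats::qnorm(clip_unit(mean(y), likelihood_params$eps))
  else kernel_config$prior_mean_value
  m0 <- rep(m0v, n)

  K <- kernel_matrix(x, x, kernel_config)
  ck <- chol_jitter(K, vi$jitter_ladder)
  Kinv <- chol2inv(ck$L)
  logdetK <- 2 * sum(log(diag(ck$L)))

  gh <- pracma::gaussHermite(vi$quad_points)
  trace_env <- new.env()
  trace_env$trace <- numeric(0)
  obj <- make_elbo(y, Kinv, logdetK, m0, likelihood_params, gh, trace_env)

  # The ELBO is multimodal when the outlier component competes with the
  # response component for high-viability wells; deterministic multi-starts
  # cover the main basins (constant prior mean; the probit of the observed
  # data; a high-side-robust start taking the minimum over duplicate doses,
  # since outliers are high-viability by model assumption). Best ELBO wins.
  ybar <- stats::ave(y, x, FUN = mean)
  ymin <- stats::ave(y, x, FUN = min)
  m_starts <- unique(list(m0,
                          stats::qnorm(clip_unit(ybar, likelihood_params$eps)),
                          stats::qnorm(clip_unit(ymin, likelihood_params$eps))))
  opt <- NULL
  for (ms in m_starts) {
    cand <- stats::optim(c(ms, rep(log(5), n)), obj$fn, obj$gr,
                         method = "L-BFGS-B",
                         lower = c(rep(-15, n), rep(-20, n)),
                         upper = c(rep(15, n), rep(20, n)),
                         control = list(maxit = vi$max_iter,
                                        factr = vi$reltol / .Machine$double.eps))
    if (is.null(opt) || cand$value < opt$value) opt <- cand
  }
  if (opt$value >= 1e10)
    stop_gpdrc("gpdrc_fit_error", "non-finite ELBO at every optimiser iterate")
  parts <- obj$eval_parts(opt$par)

  structure(list(
    train_inputs = x,
    variational_mean = parts$m_q,
    variational_cov = parts$S,
    prior_mean = m0v,
    K = K,
    Kinv = Kinv,
    jitter = ck$jitter,
    kernel_config = kernel_config,
    likelihood_params = likelihood_params,
    elbo = parts$elbo,
    elbo_trace = trace_env$trace,
    converged = opt$convergence == 0L,
    experiment = experiment
  ), class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> n = %d, elbo = %.4f%s\n",
              length(x$train_inputs), x$elbo,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Sample dose-response curves from the fitted posterior
#'
#' Draws latent curves on \code{grid} from the conditional GP given the
#' variational posterior at the training inputs, and maps them through the
#' probit link: each returned row is a viability curve \code{Phi(f*)}.
#'
#' @param posterior a [fit_gp()] result.
#' @param grid rescaled dose grid (may extend beyond the tested range).
#' @param N number of curves.
#' @param seed RNG seed; same seed gives identical draws.
#' @return \code{N x length(grid)} matrix of viabilities in (0, 1).
#' @export
sample_curves <- function(posterior, grid, N = 100L, seed = 1L) {
  x <- posterior$train_inputs
  Kinv <- posterior$Kinv
  Ksx <- kernel_matrix(grid, x, posterior$kernel_config)
  Kss <- kernel_matrix(grid, grid, posterior$kernel_config)
  A <- Ksx %*% Kinv
  mu <- posterior$prior_mean +
    as.vector(A %*% (posterior$variational_mean - posterior$prior_mean))
  Sigma <- Kss - A %*% t(Ksx) + A %*% posterior$variational_cov %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  cs <- tryCatch(chol_jitter(Sigma, c(1e-12, 1e-10, 1e-8, 1e-6)),
                 error = function(e)
                   stop_gpdrc("gpdrc_numeric_error",
                              "predictive covariance not PSD after jitter escalation"))
  set.seed(seed)
  Z <- matrix(stats::rnorm(N * length(grid)), nrow = N)
  Fs <- rep(1, N) %o% mu + Z %*% cs$L
  stats::pnorm(Fs)
}
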