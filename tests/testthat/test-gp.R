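test_that("mean-parameterised Beta density: mapping, normalisation, domain", {
  # mu = 0.5, s = 2 is the uniform distribution
  for (y in c(0.05, 0.37, 0.5, 0.93))
    expect_equal(beta_mu_logpdf(y, 0.5, 2), 0)
  # mu = 0.9, s = 11 maps to shapes (9.9, 1.1)
  expect_equal(beta_mu_logpdf(0.7, 0.9, 11), dbeta(0.7, 9.9, 1.1, log = TRUE))
  # integrates to 1 over (0,1) for random (mu, s) [quadrature oracle]
  set.seed(3)
  for (i in 1:10) {
    mu <- runif(1, 0.05, 0.95); s <- runif(1, 0.5, 80)
    q <- stats::integrate(function(y) exp(beta_mu_logpdf(y, mu, s)), 0, 1,
                          rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
  expect_error(beta_mu_logpdf(0, 0.5, 2), class = "gpdrc_domain_error")
  expect_error(beta_mu_logpdf(1, 0.5, 2), class = "gpdrc_domain_error")
})

test_that("mixture likelihood degenerates and matches hand-built densities", {
  lik1 <- mixture_likelihood_params(pi_mix = 1)
  expect_equal(mixture_loglik(0.3, 0.4, lik1),
               beta_mu_logpdf(0.3, pnorm(0.4), 50))
  # f = 0: component-1 mean is Phi(0) = 0.5; defaults give the hand-built mix
  lik <- mixture_likelihood_params()
  expect_equal(mixture_loglik(0.5, 0, lik),
               log(0.999 * dbeta(0.5, 25, 25) + 0.001 * dbeta(0.5, 9.9, 1.1)))
  ys <- c(0.1, 0.5, 0.9); fs <- c(-1, 0.3, 2)
  expect_equal(mixture_loglik(ys, fs, lik),
               log(0.999 * dbeta(ys, pnorm(fs) * 50, (1 - pnorm(fs)) * 50) +
                     0.001 * dbeta(ys, 9.9, 1.1)))
})

test_that("linear + Matern-3/2 kernel matches printed values and stays PSD", {
  cfg <- gp_kernel_config()
  expect_equal(kernel_matrix(0, 0, cfg)[1, 1], 0.2)  # linear term vanishes
  expect_equal(kernel_matrix(1, 1, cfg)[1, 1], 0.3)
  x <- c(0.2, 0.9)
  K <- kernel_matrix(x, x, cfg)
  expect_equal(K, t(K))
  r <- abs(x[1] - x[2]); z <- sqrt(3) * r / 0.3
  expect_equal(K[1, 2], 0.1 * x[1] * x[2] + 0.2 * (1 + z) * exp(-z))
  set.seed(4)
  for (i in 1:3) {
    xs <- runif(20, -0.5, 2)
    ev <- eigen(kernel_matrix(xs, xs, cfg), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("ELBO gradient agrees with central finite differences", {
  env <- asNamespace("gpdrc")
  y <- c(0.95, 0.40, 0.10); x <- c(0.3, 0.6, 1.0)
  K <- kernel_matrix(x, x)
  ck <- chol(K + diag(1e-8, 3)); Kinv <- chol2inv(ck)
  te <- new.env(); te$trace <- numeric(0)
  obj <- env$make_elbo(y, Kinv, 2 * sum(log(diag(ck))), rep(0.1, 3),
                       mixture_likelihood_params(), pracma::gaussHermite(30), te)
  par <- c(0.5, -0.2, 0.3, log(c(2, 5, 9)))
  g_num <- vapply(seq_along(par), function(i) {
    h <- 1e-6
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (obj$fn(pp) - obj$fn(pm)) / (2 * h)
  }, numeric(1))
  expect_equal(obj$gr(par), g_num, tolerance = 1e-5)
})

test_that("variational posterior matches dense-grid integration on 2 points", {
  # unimodal regime (response component only): VI should be near-exact
  lik1 <- mixture_likelihood_params(pi_mix = 1)
  e <- dose_response_experiment("c", "d", "b", c(0.1, 10), c(0.95, 0.10))
  post <- fit_gp(e, likelihood_params = lik1)
  oracle <- grid_posterior_2pt(e, post)
  expect_lt(rel_norm_err(post$variational_mean, oracle$mean), 0.05)
  expect_lt(rel_norm_err(diag(post$variational_cov), oracle$var), 0.05)
  # default mixture: the posterior gains an outlier ridge; the Gaussian fit
  # still tracks the dominant-mode mean closely
  post2 <- fit_gp(e)
  oracle2 <- grid_posterior_2pt(e, post2)
  expect_lt(rel_norm_err(post2$variational_mean, oracle2$mean), 0.05)
})

test_that("ELBO trace is finite and the final value is the best seen", {
  e <- exact_sigmoid_experiment()
  post <- fit_gp(e)
  expect_true(all(is.finite(post$elbo_trace)))
  expect_gte(post$elbo, max(post$elbo_trace) - 1e-6)
  expect_true(post$converged)
})

test_that("flat high-viability data keep the posterior-mean curve high", {
  set.seed(5)
  e <- dose_response_experiment("c", "d", "b", 10 / 2^(8:0),
                                pmin(rnorm(9, 0.95, 0.01), 1))
  post <- fit_gp(e)
  curve <- colMeans(sample_curves(post, e$dprime, N = 200, seed = 1))
  expect_true(all(curve >= 0.85 & curve <= 1))
})

test_that("conflicting duplicate-dose observations widen the posterior", {
  mk <- function(y) dose_response_experiment("c", "d", "b", c(5, rep(10, length(y))),
                                             c(0.97, y))
  lik1 <- mixture_likelihood_params(pi_mix = 1)
  both <- fit_gp(mk(c(0.9, 0.2)), likelihood_params = lik1)
  expect_true(all(is.finite(both$elbo_trace)))
  v_both <- diag(both$variational_cov)[2L]
  v_hi <- diag(fit_gp(mk(0.9), likelihood_params = lik1)$variational_cov)[2L]
  v_lo <- diag(fit_gp(mk(0.2), likelihood_params = lik1)$variational_cov)[2L]
  expect_gt(v_both, max(v_hi, v_lo))
})

test_that("posterior curve samples respect link range, seed and degeneracy", {
  e <- exact_sigmoid_experiment()
  post <- fit_gp(e)
  grid <- seq(min(e$dprime), 1.5, length.out = 50)
  s1 <- sample_curves(post, grid, N = 20, seed = 9)
  expect_true(all(s1 > 0 & s1 < 1))
  expect_identical(s1, sample_curves(post, grid, N = 20, seed = 9))
  # zero-variance posterior reproduces the probit of its mean
  degen <- post
  degen$variational_cov <- matrix(0, e$n, e$n)
  one <- sample_curves(degen, e$dprime, N = 1, seed = 1)
  expect_equal(as.numeric(one), pnorm(degen$prior_mean +
    as.numeric(kernel_matrix(e$dprime, e$dprime, post$kernel_config) %*%
                 post$Kinv %*% (post$variational_mean - post$prior_mean))),
    tolerance = 1e-4)
})

test_that("extrapolated doses carry more sampling variance than interior ones", {
  set.seed(6)
  e <- dose_response_experiment("c", "d", "b", 10 / 2^(6:0),
                                pmin(rnorm(7, 0.93, 0.02), 0.999))
  post <- fit_gp(e)
  grid <- c(0.6, 1.6)  # interior vs extrapolated
  s <- sample_curves(post, grid, N = 400, seed = 3)
  expect_gt(var(s[, 2L]), var(s[, 1L]))
})
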