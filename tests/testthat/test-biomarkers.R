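test_that("ANOVA test matches the two-sample oracle and rejects bad designs", {
  set.seed(21)
  z <- rep(c(0, 1), each = 50)
  g <- rnorm(100, 0, 1) + z * 1
  res <- anova_test(g, z)
  # closed-form two-sample computation as oracle
  d_oracle <- (mean(g[z == 1]) - mean(g[z == 0])) /
    sqrt((var(g[z == 1]) + var(g[z == 0])) / 2)
  expect_equal(res$cohens_d, d_oracle, tolerance = 1e-6)
  expect_equal(res$beta_hat, mean(g[z == 1]) - mean(g[z == 0]))
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$n_mut, 50)
  # t^2 = F for a single-df contrast
  tt <- t.test(g ~ z, var.equal = TRUE)
  expect_equal(res$F_stat, unname(tt$statistic)^2, tolerance = 1e-8)
  # collinear feature and covariate
  expect_error(anova_test(g, z, x = cbind(dup = z)), "dup",
               class = "gpdrc_rank_error")
  expect_error(anova_test(g, c(rep(1, 2), rep(0, 98))),
               class = "gpdrc_group_size_error")
})

test_that("ANOVA p-values are uniform under label permutation", {
  set.seed(22)
  g <- rnorm(60)
  z0 <- rep(c(0, 1), each = 30)
  ps <- replicate(200, anova_test(g, sample(z0))$p_value)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 1.36 / sqrt(200))  # 5% critical value
})

test_that("covariate adjustment removes tissue confounding", {
  set.seed(23)
  tissue <- rep(c("lung", "breast"), each = 40)
  z <- c(rbinom(40, 1, 0.7), rbinom(40, 1, 0.2))  # z confounded with tissue
  g <- 2 * (tissue == "lung") + rnorm(80, 0, 0.5)  # tissue effect, no z effect
  unadj <- anova_test(g, z)
  adj <- anova_test(g, z, x = tissue)
  expect_lt(abs(adj$beta_hat), abs(unadj$beta_hat))
  expect_gt(adj$p_value, 0.01)
})

test_that("sign-change probability follows the mode-opposite-mass rule", {
  set.seed(24)
  x <- rnorm(500, 0, 1)
  expect_equal(sign_change_probability(c(x, -x)), 0.5)
  expect_equal(sign_change_probability(abs(x) + 0.1), 0)
  expect_equal(sign_change_probability(c(rep(-1, 10), rep(1, 90)) +
                                         rnorm(100, 0, 0.01)), 0.10)
  expect_error(sign_change_probability(rnorm(50)), class = "gpdrc_value_error")
})

test_that("HMC log-posterior gradient matches finite differences", {
  env <- asNamespace("gpdrc")
  set.seed(25)
  n <- 40
  z <- rbinom(n, 1, 0.4)
  X <- cbind(t1 = rnorm(n))
  g <- 0.3 + 0.8 * z + rnorm(n, 0, 0.4)
  cfg <- bayes_test_config()
  model <- env$make_bayes_lp(g, z, X, runif(n, 0, 0.1)^2, cfg)
  th <- c(0.2, 0.5, -0.3, log(0.2), log(0.8))
  g_num <- vapply(seq_along(th), function(i) {
    h <- 1e-6
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (model$lp(tp) - model$lp(tm)) / (2 * h)
  }, numeric(1))
  expect_equal(model$grad(th), g_num, tolerance = 1e-5)
})

test_that("collapsed model degenerates correctly when sigma is zero or c = 0", {
  set.seed(26)
  n <- 120
  z <- rbinom(n, 1, 0.5)
  g <- 0.2 + 0.6 * z + rnorm(n, 0, 0.3)
  cfg <- function(cc) bayes_test_config(c = cc, chains = 2L, warmup = 250L,
                                        draws = 250L, seed = 3L)
  # all sigma = 0: the exponent c cannot matter (variance reduces to sigma*^2)
  r1 <- bayes_hierarchical_test(g, z, rep(0, n), config = cfg(0.25))
  r2 <- bayes_hierarchical_test(g, z, rep(0, n), config = cfg(0.9))
  expect_identical(r1$beta_samples, r2$beta_samples)
  # c = 0: the individual sigmas are ignored (permuting them changes nothing)
  sig <- runif(n, 0.05, 0.5)
  r3 <- bayes_hierarchical_test(g, z, sig, config = cfg(0))
  r4 <- bayes_hierarchical_test(g, z, sample(sig), config = cfg(0))
  expect_identical(r3$beta_samples, r4$beta_samples)
})

test_that("effect recovery, ANOVA agreement and seed reproducibility", {
  set.seed(27)
  n <- 200
  z <- rbinom(n, 1, 0.5)
  sigma <- runif(n, 0.02, 0.08)
  g <- 0.5 + 1 * z + rnorm(n, 0, sqrt(sigma^2 + 0.09))
  cfg <- bayes_test_config(chains = 2L, warmup = 400L, draws = 400L, seed = 5L)
  res <- bayes_hierarchical_test(g, z, sigma, config = cfg)
  expect_lt(abs(res$beta_mode - 1), 0.25)
  expect_lt(res$sign_change_prob, 0.01)
  expect_true(res$diagnostics$max_rhat < 1.1)
  a <- anova_test(g, z)
  expect_equal(sign(res$beta_mode), sign(a$beta_hat))
  expect_lt(abs(res$beta_mean - a$beta_hat), 0.3)
  res2 <- bayes_hierarchical_test(g, z, sigma, config = cfg)
  expect_identical(res$beta_samples, res2$beta_samples)
})

test_that("raising c monotonically discounts high-uncertainty contaminants", {
  # a contaminated mutant subgroup with sigma > 1 inflates the naive effect;
  # as c grows, sigma^c grows for sigma > 1 and the contaminants lose weight
  set.seed(28)
  n <- 150
  z <- rbinom(n, 1, 0.4)
  sigma <- rep(0.1, n)
  g <- 0.3 + 0.5 * z + rnorm(n, 0, 0.25)
  noisy <- which(z == 1)[1:8]
  sigma[noisy] <- 3
  g[noisy] <- g[noisy] + 2.5  # high-sigma mutants dragged upward
  modes <- vapply(c(0, 0.25, 0.5, 1), function(cc) {
    cfg <- bayes_test_config(c = cc, chains = 2L, warmup = 300L, draws = 300L,
                             seed = 9L)
    bayes_hierarchical_test(g, z, sigma, config = cfg)$beta_mode
  }, numeric(1))
  expect_true(all(diff(modes) < 0.03))  # monotone non-increasing up to MC noise
  expect_lt(modes[4L], modes[1L])
})

test_that("panel wrapper joins, tests, flags and BH-adjusts", {
  pan <- simulate_panel(n_cell_lines = 30L, beta_true = -1, seed = 31)
  # build a response table directly from the ground truth (fast path)
  tt <- pan$truth$table
  set.seed(32)
  responses <- data.frame(
    cell_line_id = tt$cell_line_id, drug_id = tt$drug_id,
    ic50_mean_log10uM = tt$true_log10_ic50 + rnorm(nrow(tt), 0, 0.1),
    ic50_sd = runif(nrow(tt), 0.05, 0.1), auc_mean = 0.5, auc_sd = 0.1,
    crossing_fraction = 1, within_range = TRUE, qc_spearman = -0.9,
    method = "gp", stringsAsFactors = FALSE)
  cfg <- bayes_test_config(chains = 2L, warmup = 300L, draws = 300L, seed = 1L)
  tab <- test_biomarkers(responses, pan$bem, method = "both", config = cfg)
  expect_equal(nrow(tab), 1L)
  expect_lt(tab$p, 0.01)
  expect_equal(tab$q, tab$p)  # single hypothesis: BH is identity
  expect_lt(tab$anova_beta, 0)
  expect_lt(tab$bayes_beta_mode, 0)
  expect_lt(tab$sign_change_prob, 0.05)
  expect_equal(tab$flag, "ok")
})
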