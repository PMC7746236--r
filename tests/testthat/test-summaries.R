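test_that("AUC is the mean over tested doses with sample SD across curves", {
  expect_equal(auc_from_samples(matrix(1, 1, 9))$auc_mean, 1)
  one <- auc_from_samples(matrix(c(1, 0.5, 0), 1))
  expect_equal(one$auc_mean, 0.5)
  expect_equal(one$auc_sd, 0)
  two <- auc_from_samples(rbind(rep(0.4, 5), rep(0.6, 5)))
  expect_equal(two$auc_mean, 0.5)
  expect_equal(two$auc_sd, sd(c(0.4, 0.6)))  # n-1 convention
})

test_that("IC50 extraction interpolates the first down-crossing", {
  grid <- seq(0, 2, by = 0.1)
  y <- 1 - 0.5 * grid  # crosses 0.5 exactly at d' = 1
  ic <- ic50_from_samples(matrix(y, 1), grid)
  expect_equal(ic$ic50_mean, 1)
  expect_true(ic$within_range)
  # midpoint interpolation between (0.4, 0.6) and (0.6, 0.4)
  ic2 <- ic50_from_samples(matrix(c(0.9, 0.6, 0.4), 1), c(0.2, 0.4, 0.6))
  expect_equal(ic2$ic50_mean, 0.5)
  # non-monotone curve: first crossing wins
  y3 <- c(0.9, 0.4, 0.7, 0.3)
  ic3 <- ic50_from_samples(matrix(y3, 1), c(0.25, 0.5, 0.75, 1.0))
  expect_lt(ic3$ic50_mean, 0.5)
  # never-crossing curves are excluded and produce NaN statistics
  ic4 <- ic50_from_samples(matrix(0.8, 3, 5), seq(0, 2, length.out = 5))
  expect_equal(ic4$crossing_fraction, 0)
  expect_true(is.nan(ic4$ic50_mean))
  expect_false(ic4$within_range)
  # mixed: crossing fraction counts the crossing share
  mix <- rbind(1 - 0.5 * grid, rep(0.9, length(grid)))
  expect_equal(ic50_from_samples(mix, grid)$crossing_fraction, 0.5)
})

test_that("experiment summary is deterministic and converges in N", {
  e <- exact_sigmoid_experiment(s = 0.15, p = 0.6)
  post <- fit_gp(e)
  s1 <- summarize_experiment(post, N = 100, seed = 7)
  s2 <- summarize_experiment(post, N = 100, seed = 7)
  expect_identical(s1, s2)
  expect_true(s1$within_range)
  big <- summarize_experiment(post, N = 2000, seed = 8)
  # Monte-Carlo error bound on the mean difference
  se <- s1$ic50_sd / sqrt(100) + big$ic50_sd / sqrt(2000)
  expect_lt(abs(s1$ic50_mean_log10uM - big$ic50_mean_log10uM), 4 * se + 1e-3)
  expect_lt(abs(s1$auc_mean - big$auc_mean), 0.02)
})

test_that("flat resistant truth: beyond range, AUC near 1", {
  set.seed(12)
  sim <- simulate_experiment(0.15, 2.5, dose_design(9L, 2),
                             noise_spec(beta_scale = 80, outlier_rate = 0),
                             seed = 13)
  s <- summarize_experiment(fit_gp(sim$experiment), N = 100, seed = 1)
  expect_false(s$within_range)
  expect_gte(s$auc_mean, 0.9)
})

test_that("AUC and IC50 order together across a responding panel", {
  set.seed(14)
  res <- t(sapply(1:15, function(i) {
    p <- runif(1, 0.35, 0.95)
    sim <- simulate_experiment(0.15, p, dose_design(9L, 2),
                               noise_spec(beta_scale = 60, outlier_rate = 0),
                               seed = 700 + i)
    s <- summarize_experiment(fit_gp(sim$experiment), N = 100, seed = i)
    c(ic = s$ic50_mean_log10uM, auc = s$auc_mean)
  }))
  expect_gt(cor(res[, 1L], res[, 2L], method = "spearman"), 0.9)
})

test_that("replicate decomposition separates observation from estimation", {
  mk <- function(m, s, samples) structure(
    list(ic50_mean_log10uM = m, ic50_sd = s, crossing_fraction = 1,
         ic50_samples_log10uM = samples), class = "response_summary")
  r1 <- replicate_uncertainty(list(mk(1, 0.1, rnorm(50, 1, 0.1)),
                                   mk(1, 0.1, rnorm(50, 1, 0.1)),
                                   mk(1, 0.1, rnorm(50, 1, 0.1))))
  expect_equal(r1$observation_uncertainty, 0)
  expect_equal(r1$estimation_uncertainty, 0.1)
  r2 <- replicate_uncertainty(list(mk(1, 0, rep(1, 50)), mk(2, 0, rep(2, 50))))
  expect_equal(r2$observation_uncertainty, sd(c(1, 2)))
  expect_equal(r2$estimation_uncertainty, 0)
  expect_length(r2$pooled_samples, 100L)
  # non-crossing replicates are excluded with a warning
  bad <- structure(list(ic50_mean_log10uM = NaN, ic50_sd = NaN,
                        crossing_fraction = 0,
                        ic50_samples_log10uM = numeric(0)),
                   class = "response_summary")
  expect_warning(r3 <- replicate_uncertainty(list(mk(1, 0.1, rnorm(50)),
                                                  mk(1.2, 0.1, rnorm(50)), bad)),
                 "excluded")
  expect_equal(r3$n_excluded, 1L)
  expect_error(suppressWarnings(replicate_uncertainty(list(bad, bad))),
               class = "gpdrc_value_error")
})

test_that("fit_experiments builds valid tables for both methods", {
  exps <- lapply(c(0.5, 1.6), function(p) {
    e <- exact_sigmoid_experiment(s = 0.15, p = p)
    e$cell_line_id <- sprintf("CL_%s", p)
    e
  })
  gp_tab <- fit_experiments(exps, "gp", N = 50, seed = 2)
  sg_tab <- fit_experiments(exps, "sigmoid")
  expect_equal(gp_tab$method, c("gp", "gp"))
  expect_equal(sg_tab$method, c("sigmoid", "sigmoid"))
  expect_true(gp_tab$within_range[1L])
  expect_false(sg_tab$within_range[2L])
  # sigmoid IC50 equals the back-transformed position parameter
  expect_equal(sg_tab$ic50_mean_log10uM[1L],
               dprime_to_log10uM(fit_sigmoid(exps[[1L]])$p,
                                 exps[[1L]]$max_log2_dose))
})
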