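test_that("chi-squared P-values and AIC reproduce the worked examples", {
  expect_identical(chi2_pvalue(0, 1)$p, 1)
  expect_identical(chi2_pvalue(0, 3)$p, 1)
  # chi2_2 upper tail at 2*lnLR is exp(-lnLR)
  expect_equal(chi2_pvalue(147.815, 2)$minus_log10_p, 147.815 / log(10),
               tolerance = 1e-6)
  expect_equal(chi2_pvalue(147.815, 2)$minus_log10_p, 64.19, tolerance = 1e-3)
  expect_equal(chi2_pvalue(134.89, 1)$minus_log10_p, 59.90, tolerance = 1e-3)
  # -log10 P stays exact far beyond double-precision underflow of P;
  # chi2_1 upper tail at x is 2 * Phi(-sqrt(x)), a closed form
  expect_equal(chi2_pvalue(800, 1)$minus_log10_p,
               -(log(2) + stats::pnorm(-sqrt(1600), log.p = TRUE)) / log(10),
               tolerance = 1e-10)
  expect_identical(model_aic(0, 1), 2)
  expect_equal(model_aic(134.89, 1), -267.78)
  expect_equal(model_aic(32.0, 3), -58.00)
})

test_that("the likelihood ratio is exactly zero at neutrality", {
  set.seed(2)
  traj <- simulate_trajectory_backward(0.5, selection_schedule(0.01),
                                       pop_size_history(0, 2000), 50)
  gt <- sample_ancient_genotypes(traj, sampling_schedule(c(10, 25, 40), 3))
  f <- selhmm_objective(pop_freq = 0.5, t_cutoff = 50, K = 80, N = 2000,
                        genotypes = gt)
  expect_identical(f(0), 0)
  expect_true(is.finite(f(0.05)))
  expect_identical(f(0.2), -Inf)     # outside the optimization box
})

test_that("importance-sampled ratios reduce correctly for M = 1 and duplicates", {
  set.seed(4)
  nh <- pop_size_history(0, 800)
  traj <- simulate_trajectory_backward(0.5, selection_schedule(0), nh, 200)
  traj[seq_along(traj) > 150] <- 0
  sim <- suppressMessages(simulate_structured_coalescent(
    traj, 3, 3, N_history = nh, horizon = 149))
  f1 <- selhmm_objective(pop_freq = 0.5, t_cutoff = 150, K = 60, N = 800,
                         trees = sim$events)
  f2 <- selhmm_objective(pop_freq = 0.5, t_cutoff = 150, K = 60, N = 800,
                         trees = list(sim$events, sim$events))
  expect_identical(f1(0), 0)
  for (s in c(-0.02, 0.015)) expect_equal(f1(s), f2(s), tolerance = 1e-10)
})

test_that("Brent maximization recovers closed-form optima and flags boundaries", {
  quad <- function(s) -(s - 0.013)^2
  opt <- maximize_single_epoch(quad)
  expect_equal(opt$s, 0.013, tolerance = 1e-5)
  expect_false(opt$boundary)
  mono <- function(s) 5 * s
  optm <- maximize_single_epoch(mono)
  expect_equal(optm$s, 0.1)
  expect_true(optm$boundary)
})

test_that("Nelder-Mead starts from the prescribed simplex and finds quadratic optima", {
  evals <- list()
  f <- function(s) {
    evals[[length(evals) + 1L]] <<- s
    -sum((s - c(0.02, -0.01))^2)
  }
  opt <- maximize_multi_epoch(f, 2)
  first3 <- do.call(rbind, evals[1:3])
  expect_equal(first3, rbind(c(0.01, 0), c(0, 0.01), c(0, 0)))
  expect_equal(opt$s, c(0.02, -0.01), tolerance = 1e-4)
  expect_false(any(opt$wide_uncertainty))
  # a coordinate the objective ignores is flagged as unidentified
  g <- function(s) -(s[1] - 0.01)^2
  optg <- maximize_multi_epoch(g, 2)
  expect_false(optg$wide_uncertainty[1])
  expect_true(optg$wide_uncertainty[2])
})

test_that("nested epoch models never lose likelihood ratio", {
  set.seed(6)
  traj <- simulate_trajectory_backward(0.6, selection_schedule(0.02),
                                       pop_size_history(0, 5000), 100)
  gt <- sample_ancient_genotypes(traj, sampling_schedule(seq(0, 95, 5), 2))
  f1 <- selhmm(pop_freq = 0.6, N = 5000, t_cutoff = 100, genotypes = gt, K = 120)
  f2 <- selhmm(pop_freq = 0.6, N = 5000, t_cutoff = 100, genotypes = gt,
               K = 120, time_bins = 50)
  expect_gte(f2$lnlr, f1$lnlr - 1e-3)
  expect_identical(f2$df, 2L)
  expect_equal(f2$aic, 2 * 2 - 2 * f2$lnlr)
})

test_that("importance-sampling estimates are stable in M on a fixed dataset", {
  set.seed(8)
  N <- 1000; Tn <- 120
  nh <- pop_size_history(0, N)
  traj <- simulate_trajectory_backward(0.5, selection_schedule(0), nh, Tn)
  traj[seq_along(traj) > 100] <- 0
  sims <- lapply(1:80, function(i) suppressMessages(
    simulate_structured_coalescent(traj, 3, 3, N_history = nh,
                                   horizon = Tn - 1)$events))
  fA <- selhmm_objective(pop_freq = 0.5, t_cutoff = Tn, K = 60, N = N,
                         trees = sims[1:40])
  fB <- selhmm_objective(pop_freq = 0.5, t_cutoff = Tn, K = 60, N = N,
                         trees = sims)
  s0 <- 0.02
  # Monte Carlo SE of the log of the estimator from the per-sample ratios
  lr <- attr(fB, "per_sample_loglr")(s0)
  w <- exp(lr - max(lr))
  se_log <- stats::sd(w) / (mean(w) * sqrt(length(w)))
  expect_lt(abs(fA(s0) - fB(s0)), 4 * se_log)
})

test_that("the selhmm fit object is coherent and its methods work", {
  set.seed(10)
  traj <- simulate_trajectory_backward(0.5, selection_schedule(0.03),
                                       pop_size_history(0, 8000), 80)
  gt <- sample_ancient_genotypes(traj, sampling_schedule(seq(0, 75, 5), 3))
  fit <- selhmm(pop_freq = 0.5, N = 8000, t_cutoff = 80, genotypes = gt, K = 120)
  expect_s3_class(fit, "selhmm")
  expect_gte(fit$lnlr, 0)
  expect_equal(fit$aic, 2 - 2 * fit$lnlr)
  expect_length(coef(fit), 1)
  expect_equal(as.numeric(logLik(fit)), fit$lnlr)
  expect_output(print(fit), "lnLR")
  expect_output(print(summary(fit)), "grid bins")
  expect_true(all(diff(fit$epochs$epoch_start) > 0) || fit$df == 1)
})
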