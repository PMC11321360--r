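test_that("genotype emissions follow Hardy-Weinberg weighting", {
  g <- freq_grid(5)  # x = 0, 0.1464, 0.5, 0.8536, 1
  het <- genotype_obs(0, 0, 1, 0)
  expect_equal(genotype_emission(g, het)[3], 0.5)          # 2 * 0.5 * 0.5
  dd <- genotype_obs(0, 0, 0, 1)
  expect_identical(genotype_emission(g, dd)[1], 0)         # DD impossible at x = 0
  flat <- genotype_obs(c(0, 3), c(1, 1), c(1, 1), c(1, 1))
  expect_equal(genotype_emission(g, flat), rep(1, 5))      # HWE weights sum to 1
  # common scaling of a record's likelihoods only shifts by a constant factor
  sc <- genotype_obs(0, 0.2 * 7, 0.5 * 7, 0.3 * 7)
  un <- genotype_obs(0, 0.2, 0.5, 0.3)
  expect_equal(genotype_emission(g, sc), 7 * genotype_emission(g, un))
  expect_error(genotype_obs(0, 0, 0, 0), "all-zero")
  expect_error(genotype_obs(-1, 1, 0, 0), ">= 0")
})

test_that("haplotype emissions are the one-draw analogue", {
  g <- freq_grid(5)
  der <- haplotype_obs(0, L_A = 0, L_D = 1)
  expect_equal(haplotype_emission(g, der)[2], g$x[2])
  anc <- haplotype_obs(0, L_A = 1, L_D = 0)
  expect_identical(haplotype_emission(g, anc)[1], 1)
  expect_equal(haplotype_emission(g, haplotype_obs(0, 1, 1)), rep(1, 5))
})

test_that("coalescent interval emissions match hand calculations", {
  g <- freq_grid(5)
  # two derived lineages, no events: survival at rate 1/(0.5 * 1000)
  expect_equal(interval_coalescent_emission(g, k = 3, N = 1000, n_d = 2, n_a = 1),
               exp(-1 / 500), tolerance = 1e-9)
  # one derived coalescence at offset 0.5: density then zero remaining rate
  expect_equal(interval_coalescent_emission(g, k = 3, N = 1000, n_d = 2, n_a = 1,
                                            derived = 0.5),
               0.002 * exp(-0.001), tolerance = 1e-9)
  # mixed lineage alone with one ancestral lineage away from frequency 0
  expect_identical(interval_coalescent_emission(g, k = 3, N = 1000, n_d = 1, n_a = 1), 1)
  # >= 2 derived lineages cannot coexist with frequency 0
  expect_identical(interval_coalescent_emission(g, k = 1, N = 1000, n_d = 3, n_a = 1), 0)
  # >= 2 ancestral lineages cannot coexist with frequency 1
  expect_identical(interval_coalescent_emission(g, k = 5, N = 1000, n_d = 2, n_a = 2), 0)
  # at frequency 0 with n_d = 1 the mixed lineage is treated as ancestral
  expect_equal(interval_coalescent_emission(g, k = 1, N = 1000, n_d = 1, n_a = 1,
                                            ancestral = 0.25),
               (1 / 1000) * exp(-0.25 / 1000) * exp(-0.75 * 0),
               tolerance = 1e-6)
})

test_that("survival terms compose over interval partitions", {
  g <- freq_grid(9)
  e_full <- interval_coalescent_emission(g, 5, N = 200, n_d = 3, n_a = 2)
  # same rates over (0, 0.5) and (0.5, 1): product of half-interval survivals
  lam_d <- choose(3, 2) / (g$x[5] * 200)
  lam_a <- choose(2, 2) / ((1 - g$x[5]) * 200)
  expect_equal(e_full, exp(-lam_d / 2 - lam_a / 2)^2, tolerance = 1e-12)
})

test_that("leaf multipliers and lineage-count updates behave", {
  expect_equal(leaf_emission_multiplier(0.5, 2, 1), 0.125)
  expect_identical(leaf_emission_multiplier(0.7, 0, 0), 1)
  expect_identical(leaf_emission_multiplier(0, 1, 0), 0)
})

test_that("coalescent emission matches direct structured-coalescent simulation", {
  # P(no coalescence among 3 derived in one generation at x = 0.4, N = 150)
  # and P(exactly one in the interval): compare to 1e5 direct draws
  set.seed(9)
  n <- 1e5
  lam <- choose(3, 2) / (0.4 * 150)
  t1 <- rexp(n, lam)
  p_none_emp <- mean(t1 > 1)
  g <- freq_grid(201)
  k <- nearest_bin(g, 0.4)
  x <- g$x[k]
  e_none <- interval_coalescent_emission(g, k, N = 150, n_d = 3, n_a = 1)
  lam_x <- choose(3, 2) / (x * 150)
  se <- sqrt(p_none_emp * (1 - p_none_emp) / n)
  expect_lt(abs(e_none - p_none_emp), 3 * se + abs(exp(-lam) - exp(-lam_x)))
})

test_that("schedules compile per-step products and truncate at the horizon", {
  g <- freq_grid(20)
  gt <- genotype_obs(c(0, 4.5), c(1, 0), c(0, 1), c(0, 0))
  em <- compile_emissions(g, 10, genotypes = gt)
  # age 0 -> step 2; age 4.5 -> step 6; everything else flat
  expect_equal(em$logE[, 2], log((1 - g$x)^2))
  expect_equal(em$logE[, 6], log(2 * g$x * (1 - g$x)))
  expect_true(all(em$logE[, -c(2, 6)] == 0))
  # an observation with no carrying step inside the horizon is dropped
  expect_warning(compile_emissions(g, 10, genotypes = genotype_obs(30, 1, 0, 0)),
                 "dropped")
  ev <- tree_events(der_coal = 5, anc_coal = 1200, mixed_age = 1200,
                    n_der_modern = 2, n_anc_modern = 2)
  expect_warning(
    em2 <- compile_emissions(g, 10, events = ev,
                             N_history = pop_size_history(0, 1000)),
    "horizon")
  expect_error(compile_emissions(g, 10), "data source")
})

test_that("tree emission schedules reproduce a first-principles oracle", {
  # enumerate the emissions of a small completely specified tree by hand,
  # without the schedule abstraction, and compare forward likelihoods
  g <- freq_grid(40)
  N <- 500
  nh <- pop_size_history(0, N)
  ev <- tree_events(der_coal = c(1.4, 4.3), anc_coal = c(3.2, 6.7),
                    mixed_age = 6.7, der_leaves = 2.5,
                    n_der_modern = 2, n_anc_modern = 2)
  Tn <- 12
  em <- compile_emissions(g, Tn, events = ev, N_history = nh)
  x <- g$x
  logE <- matrix(0, 40, Tn)
  hand_interval <- function(n_d, n_a, der = numeric(0), anc = numeric(0),
                            m_D = 0, m_A = 0) {
    sapply(seq_along(x), function(k)
      interval_coalescent_emission(g, k, N, n_d, n_a, der, anc)) *
      leaf_emission_multiplier(x, m_D, m_A)
  }
  logE[, 2] <- log(hand_interval(2, 2))                       # ages [0,1)
  logE[, 3] <- log(hand_interval(2, 2, der = 0.4))            # der coal at 1.4
  logE[, 4] <- log(hand_interval(1, 2, m_D = 1))              # der leaf at 2.5
  logE[, 5] <- log(hand_interval(2, 2, anc = 0.2))            # anc coal at 3.2
  logE[, 6] <- log(hand_interval(2, 1, der = 0.3))            # der coal at 4.3
  logE[, 7] <- log(hand_interval(1, 1))
  logE[, 8] <- log(hand_interval(1, 1, anc = 0.7))            # mixed coal at 6.7
  for (t in 9:Tn) logE[, t] <- log(hand_interval(0, 1))
  expect_equal(em$logE, logE, tolerance = 1e-10)
})
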