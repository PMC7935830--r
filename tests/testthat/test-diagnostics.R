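test_that("global p-value combinations follow their definitions", {
  p <- c(0.1, 0.39, 0.01)
  expect_equal(combine_gof_pvalues(p), 0.03)
  expect_equal(combine_gof_pvalues(p, "simes"), 0.03)
  expect_equal(combine_gof_pvalues(c(0.5, 0.6, 0.9)), 1)
  expect_equal(combine_gof_pvalues(c(0.04, 0.05, 0.06), "simes"),
               min(3 * 0.04, 3 * 0.05 / 2, 0.06))
  expect_true(is.na(combine_gof_pvalues(c(0.1, NA, 0.2))))
})

test_that("an observation at the center of its simulated distribution has npde near zero", {
  tight <- drv_parameters(omega_cl = 0.02, omega_v = 0.02, omega_ka = 0.02,
                          sigma_exp = 0.02, sigma_add = 0.01)
  data <- tibble::tibble(
    id = 1:5, rep = 1L, tad = c(2, 5, 9, 14, 20), dose = 800, tau = 24,
    female = 0, cyp3a5_flag = 0, slco3a1_flag = 0)
  data$dv <- css_concentration(data$tad, 12.6, 137, 0.545, 800, 24)
  res <- compute_npde(data, tight, K = 2000, seed = 1)
  expect_true(all(abs(res$table$npde) < 0.2))
  expect_true(all(res$table$pde > 0 & res$table$pde < 1))
})

test_that("npde are calibrated on self-simulated data", {
  pop <- ref_pop()
  val <- sample_validation_like(pop, n_subjects = 1e4, seed = 3)
  res <- compute_npde(val, pop, K = 1000, seed = 3)
  expect_lt(abs(mean(res$table$npde)), 0.05)
  expect_lt(abs(var(res$table$npde) - 1), 0.05)
  # pde uniform: KS statistic below the 1% critical value
  ks <- suppressWarnings(
    stats::ks.test(res$table$pde, "punif")$statistic)
  expect_lt(ks, 1.63 / sqrt(nrow(res$table)))
  expect_true(all(res$table$npde == qnorm(res$table$pde)))
})

test_that("the three-test battery keeps its nominal size under the true model", {
  pop <- ref_pop()
  rejections <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    val <- sample_validation_like(pop, n_subjects = 500, seed = 1000 + r)
    res <- compute_npde(val, pop, K = 300, seed = 2000 + r)
    if (res$p_global < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # ~5% nominal; Bonferroni is slightly conservative, binomial CI ~ +/-0.03
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.10)
})

test_that("multi-observation subjects are decorrelated before ranking", {
  pop <- ref_pop()
  s <- sample_covariates(300, seed = 12)
  sim <- simulate_profiles(s, pop, 1, c(1, 4, 19), seed = 12)
  res <- compute_npde(sim, pop, K = 500, seed = 12)
  expect_identical(nrow(res$table), nrow(sim))
  expect_lt(abs(mean(res$table$npde)), 0.1)
  expect_lt(abs(var(res$table$npde) - 1), 0.12)
})

test_that("too few observations skip the test battery with a warning", {
  pop <- ref_pop()
  data <- tibble::tibble(id = 1:2, rep = 1L, tad = c(3, 7), dv = c(3, 4),
                         dose = 800, tau = 24, female = 0, cyp3a5_flag = 0,
                         slco3a1_flag = 0)
  expect_warning(res <- compute_npde(data, pop, K = 100, seed = 1),
                 "skipped")
  expect_true(is.na(res$p_global))
  expect_error(compute_npde(data, pop, K = 50), "at least 100")
})

test_that("the pcVPC covers self-simulated data at its nominal rate", {
  pop <- ref_pop()
  val <- sample_validation_like(pop, n_subjects = 1e4, seed = 9)
  v <- pc_vpc(val, pop, K = 200, n_bins = 8, seed = 9)
  tab <- v$table
  # percentile ordering inside every bin, observed and simulated
  expect_true(all(tab$obs_p5 <= tab$obs_p50 & tab$obs_p50 <= tab$obs_p95))
  expect_true(all(tab$sim_p5_md <= tab$sim_p50_md &
                    tab$sim_p50_md <= tab$sim_p95_md))
  expect_true(all(tab$sim_p5_lo <= tab$sim_p5_hi))
  inband <- mapply(function(b, y) {
    y >= tab$sim_p5_md[tab$bin == b] & y <= tab$sim_p95_md[tab$bin == b]
  }, v$points$bin, v$points$dv_pc)
  expect_equal(mean(inband), 0.90, tolerance = 0.03 / 0.90)
})

test_that("identical population predictions make the correction factor one", {
  pop <- ref_pop()
  # all observations at the same time/covariates/regimen: PRED constant
  data <- tibble::tibble(id = 1:40, rep = 1L, tad = 5,
                         dose = 800, tau = 24, female = 0, cyp3a5_flag = 0,
                         slco3a1_flag = 0)
  set.seed(4)
  data$dv <- pmax(rnorm(40, 4, 1), 0.1)
  v <- pc_vpc(data, pop, K = 120, n_bins = 2, seed = 4)
  expect_equal(v$points$dv_pc, data$dv)
})

test_that("simulation bands widen with the additive error magnitude", {
  s <- sample_covariates(250, seed = 18)
  widths <- vapply(c(0.2, 0.611, 1.2), function(sa) {
    pop <- drv_parameters(sigma_add = sa)
    sim <- simulate_profiles(s, pop, 1, c(2, 10, 20), seed = 18)
    v <- pc_vpc(sim, pop, K = 150, n_bins = 3, seed = 18)
    mean(v$table$sim_p95_md - v$table$sim_p5_md)
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("goodness-of-fit table standardizes residuals correctly", {
  pop <- ref_pop()
  # noise-free typical-subject data: population predictions reproduce the
  # data exactly; individual predictions do when the likelihood carries a
  # vanishing residual variance (otherwise the ln-variance term pulls the
  # fit off the exact interpolation)
  data <- tibble::tibble(id = 1:3, rep = 1L, tad = c(1, 4, 19),
                         dose = 800, tau = 24, female = 0, cyp3a5_flag = 0,
                         slco3a1_flag = 0)
  data$dv <- css_concentration(data$tad, 12.6, 137, 0.545, 800, 24)
  g <- gof_table(data, pop)
  expect_equal(g$pred, g$dv)
  tight <- drv_parameters(sigma_exp = 1e-3, sigma_add = 1e-3)
  gt <- gof_table(data, tight)
  expect_equal(gt$ipred, gt$dv, tolerance = 1e-4)
  expect_true(all(abs(gt$iwres) < 0.05))
  # calibration of the variance function: residuals standardized with the
  # true parameters have unit sd on a large self-simulated set
  s <- sample_covariates(400, seed = 1)
  sim <- simulate_profiles(s, pop, 1, c(0, 0.5, 1, 2, 3, 4, 6, 9, 12, 18,
                                        21, 23), seed = 1)
  z <- (sim$dv - sim$cpred) /
    sqrt(sim$cpred^2 * pop$sigma_exp^2 + pop$sigma_add^2)
  expect_equal(sd(z), 1, tolerance = 0.05)
  # MAP-based IWRES shrink below 1 (posthoc residuals absorb noise)
  gg <- gof_table(sim, pop)
  expect_identical(nrow(gg), nrow(sim))
  expect_gt(sd(gg$iwres), 0.75)
  expect_lt(sd(gg$iwres), 1)
})
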