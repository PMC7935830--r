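test_that("default frequency table carries the learning-cohort mix", {
  fr <- covariate_frequencies()
  expect_equal(fr$p_female, 0.331)
  # categorical tables renormalized from the printed (rounded) percentages
  expect_equal(fr$cyp3a5, c(`*1/*1` = 0.260, `*1/*3` = 0.260,
                            `*3/*3` = 0.457, missing = 0.024) / 1.001)
  expect_equal(fr$slco3a1, c(GG = 0.827, GT = 0.142, TT = 0,
                             missing = 0.031))
  expect_equal(fr$regimen, c("600q12" = 0.079, "800q24" = 0.913,
                             "1200q24" = 0.008))
  expect_error(covariate_frequencies(cyp3a5 = c(a = 0.5, b = 0.4)), "sum")
})

test_that("covariate sampling recovers target frequencies and imputes genotypes", {
  n <- 1e5
  pop <- sample_covariates(n, seed = 123)
  expect_equal(mean(pop$female), 0.331, tolerance = 0.01 / 0.331)
  fr <- covariate_frequencies()
  expect_lt(abs(mean(pop$regimen == "800q24") - fr$regimen[["800q24"]]), 0.01)
  expect_lt(abs(mean(pop$race == "African") - fr$race[["African"]]), 0.01)
  # missing genotypes resolved to the modal genotype of the subject's race
  expect_false(any(pop$cyp3a5 == "missing"))
  expect_false(any(pop$slco3a1 == "missing"))
  expect_true(all(pop$cyp3a5_flag %in% 0:1))
  # *3/*3 gains the imputed missings: between raw 45.7% and 45.7+2.4%
  expect_gt(mean(pop$cyp3a5 == "*3/*3"), 0.45)
  expect_lt(mean(pop$cyp3a5 == "*3/*3"), 0.50)
})

test_that("population generation is a pure function of the seed", {
  expect_tibble_equal(sample_covariates(500, seed = 11),
                      sample_covariates(500, seed = 11))
  pop <- ref_pop()
  s <- sample_covariates(40, seed = 3)
  expect_tibble_equal(
    simulate_profiles(s, pop, 5, c(1, 4), seed = 9),
    simulate_profiles(s, pop, 5, c(1, 4), seed = 9))
})

test_that("individual draws follow the log-normal IIV model", {
  pop <- ref_pop()
  s <- ref_subject(1e5)
  d <- draw_individuals(s, pop, seed = 77)
  expect_equal(sd(log(d$cl)), 0.238, tolerance = 0.005 / 0.238)
  expect_equal(median(d$cl), 12.6, tolerance = 0.01)
  d0 <- draw_individuals(ref_subject(10), drv_parameters(
    omega_cl = 0, omega_v = 0, omega_ka = 0), seed = 1)
  expect_equal(d0$cl, rep(12.6, 10))
  expect_equal(d0$ka, rep(0.545, 10))
})

test_that("residual error has the combined exponential+additive structure", {
  pop <- ref_pop()
  none <- drv_parameters(sigma_exp = 0, sigma_add = 0)
  x <- c(0.5, 2, 8)
  expect_equal(withr::with_seed(1, apply_residual_error(x, none)), x)
  set.seed(42)
  obs <- apply_residual_error(rep(5, 1e5), pop)
  tv <- 5^2 * (exp(pop$sigma_exp^2) - 1) * exp(pop$sigma_exp^2) +
    pop$sigma_add^2
  expect_equal(var(obs), tv, tolerance = 0.05)
  expect_true(all(obs >= 1e-3))
  expect_error(apply_residual_error(-1, pop))
})

test_that("simulate_profiles draws one parameter set per subject-replicate", {
  pop <- ref_pop()
  s <- sample_covariates(127, seed = 5)
  sim <- simulate_profiles(s, pop, n_rep = 250, times = NULL, seed = 5)
  expect_identical(nrow(sim), 127L * 250L)
  expect_identical(nrow(dplyr::distinct(sim, id, rep)), 127L * 250L)
  expect_true(all(is.na(sim$dv)))
  # deterministic AUC-only mode with no IIV
  det <- simulate_profiles(s, drv_parameters(omega_cl = 0, omega_v = 0,
                                             omega_ka = 0),
                           n_rep = 1, times = NULL, seed = 1)
  tv <- individual_parameters(s, ref_pop())
  expect_equal(det$auc24_true, auc24(tv$cl, s$dose, s$tau))
})

test_that("parameter draws are shared across sampling-time sets under one seed", {
  pop <- ref_pop()
  s <- sample_covariates(30, seed = 8)
  a <- simulate_profiles(s, pop, 4, c(1, 4, 19), seed = 13)
  b <- simulate_profiles(s, pop, 4, c(0, 2), seed = 13)
  ka <- dplyr::distinct(a, id, rep, cl, v, ka)
  kb <- dplyr::distinct(b, id, rep, cl, v, ka)
  expect_tibble_equal(ka, kb)
})

test_that("validation-like sampling matches the sparse TAD model", {
  pop <- ref_pop()
  v <- sample_validation_like(pop, n_subjects = 164, seed = 21)
  expect_identical(nrow(v), 164L)
  expect_identical(anyDuplicated(v$id), 0L)
  big <- sample_validation_like(pop, n_subjects = 1e5, seed = 22)
  q24 <- big$tad[big$tau == 24]
  q12 <- big$tad[big$tau == 12]
  expect_equal(median(q24), 14.8, tolerance = 0.3 / 14.8)
  expect_true(all(q24 >= 2 & q24 <= 31.5))
  expect_true(all(q12 >= 2 & q12 <= 25.8))
  expect_true(all(big$dv >= 1e-3))
})

test_that("NONMEM-style CSV round trip is lossless", {
  pop <- ref_pop()
  s <- sample_covariates(6, seed = 2)
  sim <- simulate_profiles(s, pop, 2, c(0, 1, 4, 19), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_nmdata(sim, f)
  header <- readLines(f, n = 1)
  expect_identical(header,
    "ID,REP,TAD,DV,CPRED,AMT,II,SEX,CYP3A5,SLCO3A1,CL,V,KA,AUC24")
  back <- read_nmdata(f)
  for (col in c("tad", "dv", "cpred", "cl", "v", "ka", "auc24_true")) {
    expect_equal(back[[col]], sim[[col]], tolerance = 1e-12)
  }
  # AUC-only rows persist missing numerics as "."
  auconly <- simulate_profiles(s, pop, 1, NULL, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_nmdata(auconly, f2)
  expect_true(any(grepl(",\\.,", readLines(f2)[-1])))
  expect_true(all(is.na(read_nmdata(f2)$dv)))
})
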