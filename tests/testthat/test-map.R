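make_obs <- function(times, dv, dose = 800, tau = 24) {
  tibble::tibble(tad = times, dv = dv, dose = dose, tau = tau,
                 female = 0, cyp3a5_flag = 0, slco3a1_flag = 0)
}

test_that("with no data the prior mode is returned and the objective is the prior", {
  pop <- ref_pop()
  empty <- make_obs(numeric(0), numeric(0))
  expect_equal(map_objective(c(0, 0, 0), empty, pop), 0)
  expect_gt(map_objective(c(0.1, 0, 0), empty, pop), 0)
  expect_gt(map_objective(c(0, -0.2, 0.3), empty, pop), 0)
  fit <- map_estimate(empty, pop)
  expect_equal(fit$eta_hat, c(0, 0, 0))
  expect_equal(fit$cl_hat, 12.6)
  expect_true(fit$converged)
})

test_that("an exactly-predicted observation leaves only the ln-variance term", {
  pop <- ref_pop()
  f4 <- css_concentration(4, 12.6, 137, 0.545, 800, 24)
  obs <- make_obs(4, f4)
  g <- f4^2 * pop$sigma_exp^2 + pop$sigma_add^2
  expect_equal(map_objective(c(0, 0, 0), obs, pop), log(g))
})

test_that("random effects are recovered from noise-free rich sampling", {
  eta_true <- c(0.2, -0.1, 0.3)
  times <- c(0, 0.5, 1, 2, 3, 4, 5, 6)
  f <- css_concentration(times, 12.6 * exp(0.2), 137 * exp(-0.1),
                         0.545 * exp(0.3), 800, 24)
  # identifiability by construction: with a vanishing residual variance in
  # the likelihood the penalized fit must land on the generating etas
  tight <- drv_parameters(sigma_exp = 1e-4, sigma_add = 1e-4)
  fit <- map_estimate(make_obs(times, f), tight)
  expect_true(all(abs(fit$eta_hat - eta_true) < 0.02))
  # with the full residual variance kept in the likelihood, the same exact
  # data are shrunk toward the prior mode -- every component moves inward
  pop <- ref_pop()
  fit2 <- map_estimate(make_obs(times, f), pop)
  expect_true(fit2$converged)
  expect_true(all(abs(fit2$eta_hat) < abs(eta_true)))
  expect_true(all(fit2$eta_hat * eta_true >= 0 |
                    abs(fit2$eta_hat) < 0.05))
})

test_that("sparse data shrink the clearance estimate toward the prior", {
  pop <- ref_pop()
  eta_cl_true <- 0.6
  f0 <- css_concentration(0, 12.6 * exp(eta_cl_true), 137, 0.545, 800, 24)
  set.seed(99)
  dv <- pmax(f0 * exp(rnorm(1000, 0, pop$sigma_exp)) +
               rnorm(1000, 0, pop$sigma_add), 1e-3)
  data <- tibble::tibble(id = seq_len(1000), rep = 1L, tad = 0, dv = dv,
                         dose = 800, tau = 24, female = 0, cyp3a5_flag = 0,
                         slco3a1_flag = 0)
  fits <- map_fit(data, pop)
  expect_lt(mean(abs(fits$eta_cl)), eta_cl_true)
  expect_gt(mean(fits$eta_cl), 0)  # pulled toward but not past the prior
})

test_that("the optimizer matches a dense grid search on random sparse datasets", {
  pop <- ref_pop()
  set.seed(1234)
  for (i in 1:20) {
    nt <- sample(1:3, 1)
    times <- sort(runif(nt, 0, 24))
    eta <- rnorm(3, 0, c(0.238, 0.353, 0.575))
    f <- css_concentration(times, 12.6 * exp(eta[1]), 137 * exp(eta[2]),
                           0.545 * exp(eta[3]), 800, 24)
    dv <- pmax(f * exp(rnorm(nt, 0, pop$sigma_exp)) +
                 rnorm(nt, 0, pop$sigma_add), 1e-3)
    obs <- make_obs(times, dv)
    fit <- map_estimate(obs, pop)
    grid <- grid_map_objective(obs, pop)
    expect_lte(fit$objective, grid$value + 1e-4)
  }
})

test_that("estimation error decreases as the design gains sampling times", {
  pop <- ref_pop()
  s <- ref_subject(1)
  s$regimen <- "800q24"
  designs <- list(c(0), c(0, 4), c(1, 4, 19), c(0, 0.5, 1, 2, 3, 4, 5, 6))
  n <- 2000
  subjects <- ref_subject(n)
  mae <- vapply(designs, function(d) {
    sim <- simulate_profiles(subjects, pop, n_rep = 1, times = d, seed = 555)
    fits <- map_fit(sim, pop)
    truth <- dplyr::distinct(sim, id, eta_cl)
    mean(abs(fits$eta_cl - truth$eta_cl[match(fits$id, truth$id)]))
  }, 0)
  expect_true(all(diff(mae) < 0))
})

test_that("observation order does not affect the estimate", {
  pop <- ref_pop()
  obs <- make_obs(c(1, 4, 19), c(3.2, 4.4, 1.1))
  a <- map_estimate(obs, pop)
  b <- map_estimate(obs[c(3, 1, 2), ], pop)
  expect_identical(a$eta_hat, b$eta_hat)
  expect_identical(a$objective, b$objective)
})

test_that("batch and per-fit MAP paths agree", {
  pop <- ref_pop()
  s <- sample_covariates(15, seed = 44)
  sim <- simulate_profiles(s, pop, n_rep = 2, times = c(0, 4, 19), seed = 44)
  fb <- map_fit(sim, pop, method = "batch")
  fo <- map_fit(sim, pop, method = "optim")
  expect_equal(fb$objective, fo$objective, tolerance = 1e-6)
  expect_equal(fb$eta_cl, fo$eta_cl, tolerance = 1e-3)
  expect_equal(fb$auc_oss, fo$auc_oss, tolerance = 1e-3)
  # single-observation groups too
  sim1 <- simulate_profiles(s, pop, n_rep = 2, times = 2, seed = 45)
  fb1 <- map_fit(sim1, pop, method = "batch")
  fo1 <- map_fit(sim1, pop, method = "optim")
  expect_equal(fb1$objective, fo1$objective, tolerance = 1e-6)
})

test_that("AUC follows the MAP clearance reciprocally", {
  pop <- ref_pop()
  fit <- map_estimate(make_obs(numeric(0), numeric(0)), pop)
  expect_equal(auc_from_map(fit, dose = 800, tau = 24), 800 / 12.6)
  half <- fit
  half$cl_hat <- fit$cl_hat / 2
  expect_equal(auc_from_map(half, dose = 800, tau = 24),
               2 * auc_from_map(fit, dose = 800, tau = 24))
  expect_equal(auc_from_map(list(cl_hat = 12.6), dose = 600, tau = 12),
               1200 / 12.6)
})

test_that("tidy and glance expose the fitted quantities", {
  pop <- ref_pop()
  fit <- map_estimate(make_obs(c(1, 4), c(3, 4.5)), pop)
  td <- tidy(fit)
  expect_identical(td$term, c("eta_cl", "eta_v", "eta_ka"))
  gl <- glance(fit)
  expect_identical(names(gl), c("cl_hat", "v_hat", "ka_hat", "objective",
                                "converged", "n_obs"))
})
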