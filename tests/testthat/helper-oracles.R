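# Shared fixtures and independent oracles, built in code.

ref_pop <- function(...) drv_parameters(...)

ref_subject <- function(n = 1) {
  tibble::tibble(id = seq_len(n), female = 0, cyp3a5_flag = 0,
                 slco3a1_flag = 0, dose = 800, tau = 24)
}

# Brute-force steady state: superposition of single oral doses.
superposition_css <- function(t, cl, v, ka, dose, tau, n_doses = 200) {
  ke <- cl / v
  tp <- t %% tau
  single <- function(u) dose * ka / (v * (ka - ke)) *
    (exp(-ke * u) - exp(-ka * u))
  vapply(tp, function(x) sum(single(x + tau * (0:(n_doses - 1)))), 0)
}

# Two-stage dense grid minimizer of the MAP objective, independent of the
# package's optimizers: global coarse pass, then a fine 0.01-step pass
# around the coarse optimum.  Evaluates the penalized objective directly
# from its definition, vectorized across the grid.
grid_map_objective <- function(obs, pop, coarse = 0.04, fine = 0.01,
                               span = 4) {
  omega <- c(pop$omega_cl, pop$omega_v, pop$omega_ka)
  lim <- span * omega
  tvcl <- pop$cl_pop * (1 + pop$theta_sex * obs$female[1]) *
    (1 + pop$theta_cyp3a5 * obs$cyp3a5_flag[1])
  tvv <- pop$v_pop * (1 + pop$theta_slco3a1 * obs$slco3a1_flag[1])
  eval_grid <- function(axes) {
    g <- as.matrix(expand.grid(axes))
    vals <- g[, 1]^2 / omega[1]^2 + g[, 2]^2 / omega[2]^2 +
      g[, 3]^2 / omega[3]^2
    for (j in seq_len(nrow(obs))) {
      f <- css_concentration(obs$tad[j], tvcl * exp(g[, 1]),
                             tvv * exp(g[, 2]),
                             pop$ka_pop * exp(g[, 3]),
                             obs$dose[1], obs$tau[1])
      gv <- f^2 * pop$sigma_exp^2 + pop$sigma_add^2
      vals <- vals + (obs$dv[j] - f)^2 / gv + log(gv)
    }
    list(eta = g[which.min(vals), ], value = min(vals))
  }
  best <- eval_grid(lapply(1:3, function(k) seq(-lim[k], lim[k],
                                                by = coarse)))
  eval_grid(lapply(1:3, function(k) {
    seq(max(-lim[k], best$eta[k] - 1.5 * coarse),
        min(lim[k], best$eta[k] + 1.5 * coarse), by = fine)
  }))
}

expect_tibble_equal <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}
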