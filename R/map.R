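# Empirical-Bayes (MAP) estimation of individual random effects -- hence
# clearance and AUC -- from sparse concentration observations, with the
# population model as prior.

obs_typical <- function(obs, pop) {
  flags <- obs[1, c("female", "cyp3a5_flag", "slco3a1_flag")]
  tv <- individual_parameters(flags, pop)
  list(cl = tv$cl, v = tv$v, ka = tv$ka,
       dose = obs$dose[1], tau = obs$tau[1])
}

#' MAP objective for one observation set
#'
#' The penalized least-squares objective whose minimizer is the empirical
#' Bayes mode:
#' \deqn{O(\eta) = \sum_i \left[\frac{(y_i - f_i)^2}{g_i} + \ln g_i\right]
#'   + \sum_k \eta_k^2/\omega_k^2,}
#' with \eqn{f_i} the steady-state model prediction and
#' \eqn{g_i = f_i^2\sigma_{exp}^2 + \sigma_{add}^2} the variance-linearized
#' combined residual error.  Random effects whose \eqn{\omega} is zero are
#' fixed at 0 and excluded from the penalty.
#'
#' @param eta Length-3 numeric vector (eta_cl, eta_v, eta_ka).
#' @param obs Data frame for one subject/replicate with columns `tad`, `dv`,
#'   `dose`, `tau`, `female`, `cyp3a5_flag`, `slco3a1_flag`.  May have zero
#'   rows (prior-only objective).
#' @param pop A [drv_parameters()] object.
#' @return Scalar objective value.
#' @examples
#' pop <- drv_parameters()
#' obs <- tibble::tibble(tad = c(1, 4), dv = c(3.1, 4.7), dose = 800,
#'                       tau = 24, female = 0, cyp3a5_flag = 0,
#'                       slco3a1_flag = 0)
#' map_objective(c(0, 0, 0), obs, pop)
#' @export
map_objective <- function(eta, obs, pop) {
  stopifnot(length(eta) == 3)
  omega <- c(pop$omega_cl, pop$omega_v, pop$omega_ka)
  act <- omega > 0
  if (any(eta[!act] != 0)) {
    abort("eta components with omega = 0 are fixed at zero.")
  }
  prior <- sum(eta[act]^2 / omega[act]^2)
  if (nrow(obs) == 0) return(prior)
  tv <- obs_typical(obs, pop)
  f <- css_concentration(obs$tad, tv$cl * exp(eta[1]), tv$v * exp(eta[2]),
                         tv$ka * exp(eta[3]), tv$dose, tv$tau)
  if (any(!is.finite(f))) abort("Non-finite model prediction.")
  g <- f^2 * pop$sigma_exp^2 + pop$sigma_add^2
  sum((obs$dv - f)^2 / g + log(g)) + prior
}

#' MAP estimate for one observation set
#'
#' Minimizes [map_objective()] by quasi-Newton (BFGS) from the prior mode
#' `eta = 0` (gradient tolerance 1e-6).  If the Hessian at the solution is
#' not positive definite, a 5-point random multistart fallback is run and
#' the best mode is returned (ties broken by lowest objective, then lowest
#' `||eta||`).  With no observations the prior mode itself is returned.
#'
#' @inheritParams map_objective
#' @param seed Seed for the multistart fallback draws.
#' @return A `map_result`: `eta_hat`, `cl_hat`, `v_hat`, `ka_hat`,
#'   `objective`, `converged`, `n_obs`.
#' @examples
#' pop <- drv_parameters()
#' obs <- tibble::tibble(tad = c(1, 4, 19), dv = c(3.0, 4.5, 1.2),
#'                       dose = 800, tau = 24, female = 0,
#'                       cyp3a5_flag = 0, slco3a1_flag = 0)
#' fit <- map_estimate(obs, pop)
#' fit$cl_hat
#' @export
map_estimate <- function(obs, pop, seed = 1L) {
  omega <- c(pop$omega_cl, pop$omega_v, pop$omega_ka)
  act <- omega > 0
  tv <- if (nrow(obs)) obs_typical(obs, pop) else
    list(cl = pop$cl_pop, v = pop$v_pop, ka = pop$ka_pop,
         dose = NA_real_, tau = NA_real_)
  finish <- function(eta, objective, converged) {
    structure(list(
      eta_hat = eta,
      cl_hat = tv$cl * exp(eta[1]), v_hat = tv$v * exp(eta[2]),
      ka_hat = tv$ka * exp(eta[3]),
      objective = objective, converged = converged, n_obs = nrow(obs),
      dose = tv$dose, tau = tv$tau
    ), class = "map_result")
  }
  if (nrow(obs) == 0 || !any(act)) {
    return(finish(c(0, 0, 0), map_objective(c(0, 0, 0), obs, pop), TRUE))
  }
  fn <- function(par) {
    eta <- c(0, 0, 0); eta[act] <- par
    # non-finite predictions (overflow at extreme eta) become a finite
    # penalty so line searches can back off
    out <- tryCatch(map_objective(eta, obs, pop), error = function(e) NA)
    if (!is.finite(out)) 1e10 + sum(par^2) else out
  }
  run <- function(start) {
    optim(start, fn, method = "BFGS",
          control = list(maxit = 200, reltol = 1e-14, ndeps = rep(1e-5, sum(act))))
  }
  grad_ok <- function(par) {
    h <- 1e-5
    g <- vapply(seq_along(par), function(k) {
      e <- rep(0, length(par)); e[k] <- h
      (fn(par + e) - fn(par - e)) / (2 * h)
    }, 0)
    max(abs(g)) < 1e-6
  }
  fit <- run(rep(0, sum(act)))
  H <- try(optimHess(fit$par, fn), silent = TRUE)
  pd <- !inherits(H, "try-error") &&
    all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
  converged <- fit$convergence == 0 && pd && grad_ok(fit$par)
  if (!converged) {
    starts <- with_seed(seed, replicate(5, rnorm(sum(act), 0, omega[act]),
                                        simplify = FALSE))
    cands <- c(list(fit), lapply(starts, run))
    vals <- vapply(cands, function(z) z$value, 0)
    nrm <- vapply(cands, function(z) sum(z$par^2), 0)
    best <- order(vals, nrm)[1]
    fit <- cands[[best]]
    H <- try(optimHess(fit$par, fn), silent = TRUE)
    pd <- !inherits(H, "try-error") &&
      all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
    converged <- fit$convergence == 0 && pd
  }
  eta <- c(0, 0, 0); eta[act] <- fit$par
  finish(eta, fit$value, converged)
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("<map_result> eta = (%.4f, %.4f, %.4f)  CL = %.3f L/h  objective = %.4f  %s\n",
              x$eta_hat[1], x$eta_hat[2], x$eta_hat[3], x$cl_hat,
              x$objective, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.map_result <- function(x, ...) {
  tibble(term = c("eta_cl", "eta_v", "eta_ka"), estimate = x$eta_hat)
}

#' @export
glance.map_result <- function(x, ...) {
  tibble(cl_hat = x$cl_hat, v_hat = x$v_hat, ka_hat = x$ka_hat,
         objective = x$objective, converged = x$converged, n_obs = x$n_obs)
}

#' AUC24 from a MAP result
#'
#' Daily dose divided by the MAP clearance estimate.
#'
#' @param res A `map_result` from [map_estimate()].
#' @param dose,tau Regimen; defaults to the regimen carried by `res`.
#' @return AUC over 24 h (mg.h/L).
#' @export
auc_from_map <- function(res, dose = res$dose, tau = res$tau) {
  auc24(res$cl_hat, dose, tau)
}

# ---- vectorized batch solver -------------------------------------------

# Damped (Levenberg) Gauss-Newton on the MAP objective, run simultaneously
# for every (id, rep) group.  Groups are NA-padded to a common number of
# observations; finite-difference sensitivities of f feed an approximate
# Hessian 2 F'F/g + 2/omega^2, and steps are accepted per row only when
# they decrease the objective, so descent never relies on the
# approximation being exact.
batch_map_solve <- function(Y, Tm, tvcl, tvv, tvka, dose, tau, pop,
                            tol = 1e-6, max_iter = 100L) {
  R <- nrow(Y); J <- ncol(Y)
  W <- !is.na(Y)
  Y0 <- ifelse(W, Y, 0)
  Tm0 <- ifelse(W, Tm, 1)
  omega <- c(pop$omega_cl, pop$omega_v, pop$omega_ka)
  act <- omega > 0
  pw <- ifelse(act, 1 / pmax(omega, 1e-300)^2, 0)
  se2 <- pop$sigma_exp^2; sa2 <- pop$sigma_add^2

  fmat <- function(E1, E2, E3) {
    matrix(css_concentration(as.vector(Tm0),
                             rep(tvcl, J) * exp(as.vector(E1)),
                             rep(tvv, J) * exp(as.vector(E2)),
                             rep(tvka, J) * exp(as.vector(E3)),
                             rep(dose, J), rep(tau, J)), R, J)
  }
  # candidate etas are clamped well outside any plausible range so
  # exp(eta) can never overflow the structural model
  clamp <- function(eta) pmin(pmax(eta, -15), 15)
  objective <- function(eta) {
    Fm <- fmat(matrix(eta[, 1], R, J), matrix(eta[, 2], R, J),
               matrix(eta[, 3], R, J))
    G <- Fm^2 * se2 + sa2
    out <- rowSums(W * ((Y0 - Fm)^2 / G + log(G))) +
      (eta^2 %*% pw)[, 1]
    out[!is.finite(out)] <- .Machine$double.xmax / 2
    out
  }
  eta <- matrix(0, R, 3)
  obj <- objective(eta)
  lambda <- rep(1e-3, R)
  done <- rep(FALSE, R)
  h <- 1e-5
  for (it in seq_len(max_iter)) {
    E <- lapply(1:3, function(k) matrix(eta[, k], R, J))
    Fm <- fmat(E[[1]], E[[2]], E[[3]])
    G <- Fm^2 * se2 + sa2
    Rm <- (Y0 - Fm) * W
    # sensitivities dF/deta_k by central differences (inactive dims -> 0)
    Fd <- vector("list", 3)
    for (k in 1:3) {
      if (!act[k]) { Fd[[k]] <- matrix(0, R, J); next }
      Ep <- E; Ep[[k]] <- Ep[[k]] + h
      Em <- E; Em[[k]] <- Em[[k]] - h
      Fd[[k]] <- (fmat(Ep[[1]], Ep[[2]], Ep[[3]]) -
                  fmat(Em[[1]], Em[[2]], Em[[3]])) / (2 * h)
    }
    Gp <- lapply(Fd, function(Fk) 2 * Fm * se2 * Fk)
    grad <- sapply(1:3, function(k) {
      rowSums(W * (-2 * Rm * Fd[[k]] / G - Rm^2 * Gp[[k]] / G^2 +
                     Gp[[k]] / G)) + 2 * eta[, k] * pw[k]
    })
    gmax <- apply(abs(grad), 1, max)
    done <- done | gmax < tol
    if (all(done)) break
    # Gauss-Newton Hessian blocks (per row)
    Hk <- function(k, l) rowSums(W * 2 * Fd[[k]] * Fd[[l]] / G) +
      if (k == l) 2 * pw[k] else 0
    h11 <- Hk(1, 1); h22 <- Hk(2, 2); h33 <- Hk(3, 3)
    h12 <- Hk(1, 2); h13 <- Hk(1, 3); h23 <- Hk(2, 3)
    # inactive dims: identity row/col, zero gradient
    for (k in which(!act)) {
      if (k == 1) { h11 <- h11 + 1; h12 <- 0 * h12; h13 <- 0 * h13 }
      if (k == 2) { h22 <- h22 + 1; h12 <- 0 * h12; h23 <- 0 * h23 }
      if (k == 3) { h33 <- h33 + 1; h13 <- 0 * h13; h23 <- 0 * h23 }
    }
    d11 <- h11 * (1 + lambda); d22 <- h22 * (1 + lambda)
    d33 <- h33 * (1 + lambda)
    # closed-form 3x3 solve via cofactors, vectorized over rows
    det3 <- d11 * (d22 * d33 - h23^2) - h12 * (h12 * d33 - h23 * h13) +
      h13 * (h12 * h23 - d22 * h13)
    det3[abs(det3) < 1e-300] <- 1e-300
    b1 <- -grad[, 1]; b2 <- -grad[, 2]; b3 <- -grad[, 3]
    s1 <- (b1 * (d22 * d33 - h23^2) + b2 * (h13 * h23 - h12 * d33) +
             b3 * (h12 * h23 - h13 * d22)) / det3
    s2 <- (b1 * (h23 * h13 - h12 * d33) + b2 * (d11 * d33 - h13^2) +
             b3 * (h13 * h12 - d11 * h23)) / det3
    s3 <- (b1 * (h12 * h23 - d22 * h13) + b2 * (h12 * h13 - d11 * h23) +
             b3 * (d11 * d22 - h12^2)) / det3
    step <- cbind(s1, s2, s3)
    step[, !act] <- 0
    step[done, ] <- 0
    cand <- clamp(eta + step)
    obj_new <- objective(cand)
    improved <- !done & is.finite(obj_new) & (obj_new < obj)
    eta[improved, ] <- cand[improved, ]
    obj[improved] <- obj_new[improved]
    lambda[improved] <- pmax(lambda[improved] / 3, 1e-10)
    lambda[!improved & !done] <- pmin(lambda[!improved & !done] * 10, 1e10)
    done <- done | (!improved & lambda >= 1e10)
    small <- rowSums(step^2) < 1e-24
    done <- done | (improved & small & gmax < 1e-4)
  }
  list(eta = eta, objective = obj, converged = gmax_final(eta, objective, tol))
}

gmax_final <- function(eta, objective, tol) {
  # confirm convergence with a fresh central-difference gradient
  h <- 1e-5
  R <- nrow(eta)
  g <- matrix(0, R, 3)
  for (k in 1:3) {
    ep <- eta; ep[, k] <- ep[, k] + h
    em <- eta; em[, k] <- em[, k] - h
    g[, k] <- (objective(ep) - objective(em)) / (2 * h)
  }
  apply(abs(g), 1, max) < 1e-4
}

#' Batch MAP fit over a simulated dataset
#'
#' Runs MAP estimation for every `(id, rep)` group of a long-format dataset
#' (as produced by [simulate_profiles()] or [sample_validation_like()]).
#' The default path is a vectorized damped Gauss-Newton solver across all
#' groups simultaneously; any group it flags as non-converged is re-fitted
#' with the per-group quasi-Newton [map_estimate()] path, and flagged in
#' the output if still unconverged.  `method = "optim"` forces the
#' per-group path for everything.
#'
#' @param data Long-format observations: columns `id`, `rep`, `tad`, `dv`,
#'   `dose`, `tau`, `female`, `cyp3a5_flag`, `slco3a1_flag` (and optionally
#'   `auc24_true`, carried through).
#' @param pop A [drv_parameters()] object.
#' @param method `"batch"` (default) or `"optim"`.
#' @return Tibble, one row per (id, rep): `eta_cl`, `eta_v`, `eta_ka`,
#'   `cl_hat`, `v_hat`, `ka_hat`, `objective`, `converged`, `auc_oss`.
#' @examples
#' subj <- sample_covariates(5, seed = 3)
#' sim <- simulate_profiles(subj, drv_parameters(), 2, c(1, 4, 19), seed = 3)
#' map_fit(sim, drv_parameters())
#' @export
map_fit <- function(data, pop, method = c("batch", "optim")) {
  method <- match.arg(method)
  data <- dplyr::arrange(as_tibble(data), .data$id, .data$rep, .data$tad)
  keys <- dplyr::distinct(
    data, .data$id, .data$rep, .data$dose, .data$tau, .data$female,
    .data$cyp3a5_flag, .data$slco3a1_flag,
    dplyr::across(dplyr::any_of("auc24_true")))
  if (anyDuplicated(keys[c("id", "rep")])) {
    abort("Each (id, rep) group must have constant regimen and covariates.")
  }
  if (method == "optim") {
    groups <- split(data, interaction(data$id, data$rep, drop = TRUE,
                                      lex.order = TRUE))
    res <- purrr::map(groups, function(g) {
      fit <- map_estimate(g, pop)
      tibble(id = g$id[1], rep = g$rep[1],
             eta_cl = fit$eta_hat[1], eta_v = fit$eta_hat[2],
             eta_ka = fit$eta_hat[3], cl_hat = fit$cl_hat,
             v_hat = fit$v_hat, ka_hat = fit$ka_hat,
             objective = fit$objective, converged = fit$converged)
    })
    out <- dplyr::bind_rows(res)
    out <- dplyr::left_join(out, keys, by = c("id", "rep"))
    out$auc_oss <- auc24(out$cl_hat, out$dose, out$tau)
    return(dplyr::arrange(out, .data$id, .data$rep))
  }
  # batch path: NA-pad groups to a common width
  keys <- dplyr::arrange(keys, .data$id, .data$rep)
  grp <- paste(data$id, data$rep, sep = "\r")
  grp_keys <- paste(keys$id, keys$rep, sep = "\r")
  gidx <- match(grp, grp_keys)
  counts <- tabulate(gidx, nbins = nrow(keys))
  J <- max(counts)
  pos <- sequence(rle(gidx)$lengths)  # data sorted by id, rep, tad
  Y <- matrix(NA_real_, nrow(keys), J)
  Tm <- matrix(NA_real_, nrow(keys), J)
  Y[cbind(gidx, pos)] <- data$dv
  Tm[cbind(gidx, pos)] <- data$tad
  tv <- individual_parameters(keys, pop)
  sol <- batch_map_solve(Y, Tm, tv$cl, tv$v, tv$ka, keys$dose, keys$tau, pop)
  out <- keys
  out$eta_cl <- sol$eta[, 1]; out$eta_v <- sol$eta[, 2]
  out$eta_ka <- sol$eta[, 3]
  out$objective <- sol$objective
  out$converged <- sol$converged
  # refit stragglers with the reference per-group path
  bad <- which(!out$converged)
  if (length(bad)) {
    for (b in bad) {
      g <- data[gidx == b, ]
      fit <- map_estimate(g, pop)
      if (fit$objective <= out$objective[b] + 1e-10) {
        out$eta_cl[b] <- fit$eta_hat[1]; out$eta_v[b] <- fit$eta_hat[2]
        out$eta_ka[b] <- fit$eta_hat[3]
        out$objective[b] <- fit$objective
        out$converged[b] <- fit$converged
      }
    }
  }
  out$cl_hat <- tv$cl * exp(out$eta_cl)
  out$v_hat <- tv$v * exp(out$eta_v)
  out$ka_hat <- tv$ka * exp(out$eta_ka)
  out$auc_oss <- auc24(out$cl_hat, out$dose, out$tau)
  dplyr::arrange(out, .data$id, .data$rep)
}
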