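# Synthetic population generator: covariates, regimens, individual
# parameters and simulated concentration datasets with the statistical
# structure of the learning and validation cohorts.

#' Covariate and regimen frequency table
#'
#' Default frequencies reproduce the learning cohort: 33.1% women; CYP3A5
#' *1/*1 26.0%, *1/*3 26.0%, *3/*3 45.7%, missing 2.4%; SLCO3A1 rs8027174
#' GG 82.7%, GT 14.2%, TT 0%, missing 3.1%; race Caucasian 52.8%, African
#' 43.3%, other 3.9%; regimens 600 mg q12h 7.9%, 800 mg q24h 91.3%,
#' 1200 mg q24h 0.8%.  Each categorical distribution is validated (raw sum
#' within 0.5% of one, to absorb printed rounding) and renormalized exactly.
#'
#' @param p_female Proportion of women.
#' @param cyp3a5,slco3a1,race,regimen Named numeric probability vectors.
#' @return A `covariate_frequencies` object.
#' @examples
#' covariate_frequencies()
#' @export
covariate_frequencies <- function(
    p_female = 0.331,
    cyp3a5 = c("*1/*1" = 0.260, "*1/*3" = 0.260, "*3/*3" = 0.457,
               missing = 0.024),
    slco3a1 = c(GG = 0.827, GT = 0.142, TT = 0, missing = 0.031),
    race = c(Caucasian = 0.528, African = 0.433, Other = 0.039),
    regimen = c("600q12" = 0.079, "800q24" = 0.913, "1200q24" = 0.008)) {
  check_number(p_female, "p_female", lower = 0, upper = 1)
  norm <- function(p, nm) {
    if (is.null(names(p)) || anyNA(p) || any(p < 0)) {
      abort(sprintf("`%s` must be a named non-negative probability vector.", nm))
    }
    s <- sum(p)
    if (abs(s - 1) > 0.005) {
      abort(sprintf("`%s` must sum to 1 (got %.4f).", nm, s))
    }
    p / s
  }
  structure(list(
    p_female = p_female,
    cyp3a5 = norm(cyp3a5, "cyp3a5"),
    slco3a1 = norm(slco3a1, "slco3a1"),
    race = norm(race, "race"),
    regimen = norm(regimen, "regimen")
  ), class = "covariate_frequencies")
}

regimen_lookup <- function(labels) {
  tab <- list("600q12" = c(600, 12), "800q24" = c(800, 24),
              "1200q24" = c(1200, 24))
  bad <- setdiff(unique(labels), names(tab))
  if (length(bad)) abort(paste0("Unknown regimen label(s): ",
                                paste(bad, collapse = ", ")))
  m <- do.call(rbind, tab[labels])
  tibble(dose = unname(m[, 1]), tau = unname(m[, 2]))
}

sample_categorical <- function(n, p) {
  names(p)[1L + findInterval(runif(n), cumsum(p), left.open = TRUE)]
}

# Modal non-missing genotype within each race of the drawn sample; falls
# back to the overall mode when a race has no observed genotypes.
impute_modal <- function(geno, race) {
  obs <- geno != "missing"
  if (!any(obs)) abort("All genotypes missing; cannot impute.")
  overall <- names(which.max(table(geno[obs])))
  for (r in unique(race[!obs])) {
    sel <- race == r & obs
    mode_r <- if (any(sel)) names(which.max(table(geno[sel]))) else overall
    geno[race == r & !obs] <- mode_r
  }
  geno
}

#' Draw virtual subjects with covariates and regimens
#'
#' Independent categorical draws from a [covariate_frequencies()] table.
#' Genotypes drawn as "missing" are imputed with the most frequent observed
#' genotype among subjects of the same race (mirroring the handling of
#' missing genotypes in the validation cohort), so indicator flags are
#' always resolved.  `cyp3a5_flag` is 1 for *3/*3 non-expressers;
#' `slco3a1_flag` is 1 for T-allele carriers (GT or TT).
#'
#' @param n Number of subjects.
#' @param freq A [covariate_frequencies()] table.
#' @param seed Integer seed; identical seeds give identical populations.
#' @return Tibble with one row per subject: `id`, `female`, `race`,
#'   `cyp3a5`, `slco3a1`, `cyp3a5_flag`, `slco3a1_flag`, `regimen`,
#'   `dose`, `tau`.
#' @examples
#' sample_covariates(5, seed = 42)
#' @export
sample_covariates <- function(n, freq = covariate_frequencies(), seed = 1) {
  if (!inherits(freq, "covariate_frequencies")) {
    abort("`freq` must be a covariate_frequencies() table.")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  with_seed(seed, {
    female <- as.integer(runif(n) < freq$p_female)
    race <- sample_categorical(n, freq$race)
    cyp <- impute_modal(sample_categorical(n, freq$cyp3a5), race)
    slc <- impute_modal(sample_categorical(n, freq$slco3a1), race)
    reg <- sample_categorical(n, freq$regimen)
    dt <- regimen_lookup(reg)
    tibble(
      id = seq_len(n), female = female, race = race,
      cyp3a5 = cyp, slco3a1 = slc,
      cyp3a5_flag = as.integer(cyp == "*3/*3"),
      slco3a1_flag = as.integer(slc %in% c("GT", "TT")),
      regimen = reg, dose = dt$dose, tau = dt$tau
    )
  })
}

#' Draw individual parameters with log-normal inter-individual variability
#'
#' Adds independent random effects `eta ~ N(0, omega^2)` per parameter
#' (no correlations: none are part of the model) and derives `cl`, `v`,
#' `ka` via [individual_parameters()].
#'
#' @param subjects Tibble from [sample_covariates()] (or any data frame with
#'   the indicator columns).
#' @param pop A [drv_parameters()] object.
#' @param seed Integer seed.
#' @return `subjects` with `eta_*`, `cl`, `v`, `ka` columns.
#' @export
draw_individuals <- function(subjects, pop, seed = 1) {
  n <- nrow(subjects)
  with_seed(seed, {
    em <- cbind(rnorm(n, 0, pop$omega_cl),
                rnorm(n, 0, pop$omega_v),
                rnorm(n, 0, pop$omega_ka))
    individual_parameters(subjects, pop, eta = em)
  })
}

#' Apply combined exponential + additive residual error
#'
#' Observed concentration is `c_pred * exp(e1) + e2` with
#' `e1 ~ N(0, sigma_exp^2)` and `e2 ~ N(0, sigma_add^2)`.  Values below the
#' positivity floor are set to the floor (0.001 mg/L by default, below any
#' plausible assay quantification limit for darunavir).
#'
#' @param c_pred Model-predicted concentrations (>= 0), vectorized.
#' @param pop A [drv_parameters()] object (uses `sigma_exp`, `sigma_add`).
#' @param floor Positivity floor (mg/L).
#' @return Observed concentrations, same length as `c_pred`.  Uses the
#'   current RNG state (wrap in a seeded context for reproducibility).
#' @export
apply_residual_error <- function(c_pred, pop, floor = 1e-3) {
  if (any(c_pred < 0)) abort("`c_pred` must be non-negative.")
  n <- length(c_pred)
  obs <- c_pred * exp(rnorm(n, 0, pop$sigma_exp)) + rnorm(n, 0, pop$sigma_add)
  pmax(obs, floor)
}

#' Simulate replicate steady-state concentration profiles
#'
#' For each subject x replicate: a fresh random-effect draw, concentrations
#' at the requested times after dose (with residual error), and the true
#' AUC24 implied by the drawn clearance.  With `times = NULL` or empty, an
#' AUC-only dataset (parameter draws without observations) is returned.
#'
#' Random-effect draws consume the RNG stream before any residual-error
#' draws (which use a derived sub-stream), so two calls with the same
#' `subjects`, `n_rep` and `seed` but different `times` share identical
#' parameter draws.  This makes sampling-strategy comparisons paired.
#'
#' @param subjects Tibble from [sample_covariates()].
#' @param pop A [drv_parameters()] object.
#' @param n_rep Replicate profiles per subject.
#' @param times Sampling times after dose (h), each in `[0, 24]`.
#' @param seed Integer seed.
#' @param floor Positivity floor passed to [apply_residual_error()].
#' @return Tibble with one row per (subject, replicate, time): `id`, `rep`,
#'   `tad`, `dv` (observed), `cpred` (noise-free), `dose`, `tau`, indicator
#'   columns, true `cl`, `v`, `ka` and `auc24_true`.  In AUC-only mode, one
#'   row per (subject, replicate) with `tad`/`dv`/`cpred` = `NA`.
#' @examples
#' subj <- sample_covariates(4, seed = 7)
#' simulate_profiles(subj, drv_parameters(), n_rep = 2,
#'                   times = c(1, 4, 19), seed = 7)
#' @export
simulate_profiles <- function(subjects, pop, n_rep, times, seed = 1,
                              floor = 1e-3) {
  if (!is.null(times) && length(times) &&
      (any(times < 0) || any(times > 24))) {
    abort("`times` must lie in [0, 24] hours.")
  }
  n_sub <- nrow(subjects)
  grid <- tidyr::expand_grid(id = subjects$id, rep = seq_len(n_rep))
  base <- dplyr::left_join(grid, subjects, by = "id")
  # eta stream first (strategy-independent), replicate-major within subject
  draws <- with_seed(seed, {
    cbind(rnorm(n_sub * n_rep, 0, pop$omega_cl),
          rnorm(n_sub * n_rep, 0, pop$omega_v),
          rnorm(n_sub * n_rep, 0, pop$omega_ka))
  })
  base <- individual_parameters(base, pop, eta = draws)
  base$auc24_true <- auc24(base$cl, base$dose, base$tau)
  if (is.null(times) || !length(times)) {
    base$tad <- NA_real_; base$cpred <- NA_real_; base$dv <- NA_real_
    return(dplyr::relocate(base, "id", "rep", "tad", "dv", "cpred"))
  }
  long <- tidyr::expand_grid(
    dplyr::select(base, "id", "rep"), tad = as.numeric(sort(times)))
  long <- dplyr::left_join(long, base, by = c("id", "rep"))
  long$cpred <- css_concentration(long$tad, long$cl, long$v, long$ka,
                                  long$dose, long$tau)
  long$dv <- with_seed(derive_seed(seed, c(2L, length(times))),
                       apply_residual_error(long$cpred, pop, floor = floor))
  dplyr::relocate(long, "id", "rep", "tad", "dv", "cpred")
}

# Truncated log-normal TAD model for sparse validation-like sampling:
# mu = log(median); sigma from P(X <= max) = 0.975 before truncation.
tad_model <- function(tau) {
  if (tau == 24) list(mu = log(14.8), sigma = log(31.5 / 14.8) / qnorm(0.975),
                      lo = 2, hi = 31.5)
  else list(mu = log(13.7), sigma = log(25.8 / 13.7) / qnorm(0.975),
            lo = 2, hi = 25.8)
}

rtrunc_lnorm <- function(n, mu, sigma, lo, hi) {
  p <- plnorm(c(lo, hi), mu, sigma)
  qlnorm(p[1] + runif(n) * (p[2] - p[1]), mu, sigma)
}

#' Simulate a sparse validation-like dataset
#'
#' One observation per subject at a random post-intake time, emulating
#' sparse therapeutic-drug-monitoring sampling: time after dose drawn from
#' a truncated log-normal with median 14.8 h on \[2, 31.5\] for q24h
#' regimens and median 13.7 h on \[2, 25.8\] for q12h regimens.  Post-intake
#' times beyond the dosing interval (a delayed next intake) are evaluated on
#' the periodic steady-state profile.
#'
#' @param pop A [drv_parameters()] object.
#' @param n_subjects Number of subjects (the validation cohort had 164).
#' @param freq Covariate frequency table for the drawn subjects.
#' @param seed Integer seed.
#' @param floor Positivity floor.
#' @return Tibble, one row per subject, same columns as
#'   [simulate_profiles()].
#' @export
sample_validation_like <- function(pop, n_subjects = 164,
                                   freq = covariate_frequencies(),
                                   seed = 1, floor = 1e-3) {
  subjects <- sample_covariates(n_subjects, freq, seed = derive_seed(seed, 11L))
  base <- draw_individuals(subjects, pop, seed = derive_seed(seed, 12L))
  base$rep <- 1L
  base$auc24_true <- auc24(base$cl, base$dose, base$tau)
  base$tad <- with_seed(derive_seed(seed, 13L), {
    tad <- numeric(n_subjects)
    for (tt in unique(base$tau)) {
      m <- tad_model(tt)
      idx <- which(base$tau == tt)
      tad[idx] <- rtrunc_lnorm(length(idx), m$mu, m$sigma, m$lo, m$hi)
    }
    tad
  })
  base$cpred <- css_concentration(base$tad, base$cl, base$v, base$ka,
                                  base$dose, base$tau)
  base$dv <- with_seed(derive_seed(seed, 14L),
                       apply_residual_error(base$cpred, pop, floor = floor))
  dplyr::relocate(as_tibble(base), "id", "rep", "tad", "dv", "cpred")
}
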