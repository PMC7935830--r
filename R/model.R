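# Structural model: one-compartment, first-order absorption and elimination,
# multiple oral dosing at steady state.

#' Steady-state concentration of the one-compartment oral model
#'
#' Evaluates the analytic steady-state concentration of a one-compartment
#' model with first-order absorption (rate `ka`) and first-order elimination
#' (rate `ke = cl / v`) under repeated dosing of `dose` mg every `tau` hours:
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)}\left[
#'   \frac{e^{-k_e t'}}{1 - e^{-k_e \tau}} -
#'   \frac{e^{-k_a t'}}{1 - e^{-k_a \tau}}\right],\quad t' = t \bmod \tau.}
#' Times are hours after a (reference) dose; times beyond `tau` wrap around
#' the dosing interval, so a pre-dose trough can be requested either as
#' `t = 0` or `t = tau`.  When `ka` and `ke` are closer than `1e-8` /h the
#' analytic equal-rates limit is used.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param t Time after dose (h), non-negative.
#' @param cl,v,ka Individual apparent clearance (L/h), volume (L) and
#'   absorption rate constant (1/h).
#' @param dose Dose amount per administration (mg).
#' @param tau Dosing interval (h).
#' @return Concentration (mg/L), same length as the recycled inputs.
#' @examples
#' css_concentration(c(0, 1, 4, 19), cl = 12.6, v = 137, ka = 0.545,
#'                   dose = 800, tau = 24)
#' @export
css_concentration <- function(t, cl, v, ka, dose, tau) {
  n <- max(length(t), length(cl), length(v), length(ka),
           length(dose), length(tau))
  t <- rep_len(t, n); cl <- rep_len(cl, n); v <- rep_len(v, n)
  ka <- rep_len(ka, n); dose <- rep_len(dose, n); tau <- rep_len(tau, n)
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and non-negative.")
  }
  if (any(!is.finite(cl) | !is.finite(v) | !is.finite(ka) |
          !is.finite(dose) | !is.finite(tau)) ||
      any(cl <= 0 | v <= 0 | ka <= 0 | dose <= 0 | tau <= 0)) {
    abort("PK parameters, dose and tau must be finite and positive.")
  }
  ke <- cl / v
  tp <- t %% tau
  # wrap exact multiples of tau to the trough (t' = tau side is identical
  # by periodicity; %% already returns 0 there, which is the same value)
  out <- numeric(n)
  deg <- abs(ka - ke) < 1e-8
  if (any(!deg)) {
    i <- which(!deg)
    out[i] <- dose[i] * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * tp[i]) / (1 - exp(-ke[i] * tau[i])) -
       exp(-ka[i] * tp[i]) / (1 - exp(-ka[i] * tau[i])))
  }
  if (any(deg)) {
    # limit ka -> ke = k of the two-exponential solution:
    # C = (D k / V) * e^{-k t'} / (1-e^{-k tau}) *
    #     [ t' - tau e^{-k tau}/(1-e^{-k tau}) + 1/k - 1/k ] ... derived via
    # l'Hopital; compact closed form below.
    i <- which(deg)
    k <- (ka[i] + ke[i]) / 2
    E <- exp(-k * tp[i]); Et <- exp(-k * tau[i]); q <- 1 - Et
    out[i] <- dose[i] * k / v[i] * E / q * (tp[i] + tau[i] * Et / q)
  }
  pmax(out, 0)
}

#' Steady-state 24-hour area under the curve
#'
#' At steady state with linear elimination the 24-h AUC equals daily dose
#' divided by clearance, independent of `v` and `ka`.
#'
#' @param cl Apparent clearance (L/h); vectorized.
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (h).
#' @return AUC over 24 h (mg.h/L).
#' @examples
#' auc24(12.6, dose = 800, tau = 24) # 800 / 12.6
#' auc24(12.6, dose = 600, tau = 12) # 1200 / 12.6
#' @export
auc24 <- function(cl, dose, tau) {
  if (any(cl <= 0)) abort("`cl` must be positive.")
  (dose * 24 / tau) / cl
}

#' Clinically meaningful AUC range predicate
#'
#' Flags 24-h AUC values inside the 50-130 mg.h/L window (the 95% prediction
#' interval of exposure in the learning population) used to summarize
#' limited-sampling performance on clinically typical exposures.
#'
#' @param auc AUC24 values (mg.h/L).
#' @return Logical vector.
#' @export
auc_in_clinical_range <- function(auc) {
  auc >= 50 & auc <= 130
}

#' Individual PK parameters from covariates and random effects
#'
#' Applies the proportional covariate model and log-normal random effects to
#' the typical values:
#' `cl = cl_pop * (1 + theta_sex * female) * (1 + theta_cyp3a5 * cyp3a5_flag) * exp(eta1)`,
#' `v  = v_pop  * (1 + theta_slco3a1 * slco3a1_flag) * exp(eta2)`,
#' `ka = ka_pop * exp(eta3)`.
#'
#' @param data A data frame with columns `female`, `cyp3a5_flag`,
#'   `slco3a1_flag` (0/1 indicators, no missing values: genotypes must be
#'   imputed first, see [sample_covariates()]).
#' @param pop A [drv_parameters()] object.
#' @param eta Either `NULL` (all random effects zero), a length-3 numeric
#'   vector applied to every row, or an `nrow(data)` x 3 matrix with columns
#'   (eta_cl, eta_v, eta_ka).
#' @return `data` as a tibble with columns `cl`, `v`, `ka` added (and
#'   `eta_cl`, `eta_v`, `eta_ka` when `eta` is supplied).
#' @examples
#' ref <- tibble::tibble(female = 0, cyp3a5_flag = 0, slco3a1_flag = 0)
#' individual_parameters(ref, drv_parameters())
#' @export
individual_parameters <- function(data, pop, eta = NULL) {
  data <- as_tibble(data)
  for (nm in c("female", "cyp3a5_flag", "slco3a1_flag")) {
    if (!nm %in% names(data)) {
      abort(sprintf("`data` must contain column `%s`.", nm))
    }
    x <- data[[nm]]
    if (anyNA(x)) {
      abort(sprintf(
        "Missing values in `%s`: genotype imputation must be applied before deriving parameters.",
        nm))
    }
    if (!all(x %in% c(0, 1))) {
      abort(sprintf("`%s` must be a 0/1 indicator.", nm))
    }
  }
  n <- nrow(data)
  if (is.null(eta)) {
    em <- matrix(0, n, 3)
    keep_eta <- FALSE
  } else if (is.matrix(eta)) {
    stopifnot(nrow(eta) == n, ncol(eta) == 3)
    em <- eta
    keep_eta <- TRUE
  } else {
    stopifnot(length(eta) == 3)
    em <- matrix(rep(as.numeric(eta), each = n), n, 3)
    keep_eta <- TRUE
  }
  data$cl <- pop$cl_pop * (1 + pop$theta_sex * data$female) *
    (1 + pop$theta_cyp3a5 * data$cyp3a5_flag) * exp(em[, 1])
  data$v <- pop$v_pop * (1 + pop$theta_slco3a1 * data$slco3a1_flag) *
    exp(em[, 2])
  data$ka <- pop$ka_pop * exp(em[, 3])
  if (keep_eta) {
    data$eta_cl <- em[, 1]; data$eta_v <- em[, 2]; data$eta_ka <- em[, 3]
  }
  data
}

#' Predict steady-state concentrations for a long-format dataset
#'
#' Convenience wrapper: evaluates [css_concentration()] row-wise on a data
#' frame carrying columns `tad`, `cl`, `v`, `ka`, `dose`, `tau`.
#'
#' @param data Data frame with the columns above.
#' @param pop Optional [drv_parameters()]; when supplied and `cl`/`v`/`ka`
#'   are absent, typical-value parameters are derived from the covariate
#'   columns via [individual_parameters()].
#' @return `data` with a `cpred` column added.
#' @export
predict_concentration <- function(data, pop = NULL) {
  data <- as_tibble(data)
  if (!all(c("cl", "v", "ka") %in% names(data))) {
    if (is.null(pop)) {
      abort("Supply `pop` to derive parameters, or provide cl/v/ka columns.")
    }
    data <- individual_parameters(data, pop)
  }
  data$cpred <- css_concentration(data$tad, data$cl, data$v, data$ka,
                                  data$dose, data$tau)
  data
}
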