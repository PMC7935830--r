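# Goodness-of-fit table: population and individual predictions and
# individual weighted residuals.

#' Population/individual predictions and residual summaries
#'
#' Computes, for every observation, the population prediction `pred`
#' (random effects at zero, subject covariates applied), the individual
#' prediction `ipred` (random effects at their MAP estimates from
#' [map_fit()]), and the individual weighted residual
#' `iwres = (dv - ipred) / sqrt(ipred^2 sigma_exp^2 + sigma_add^2)`.
#' Conditional weighted residuals (which require a different linearization)
#' are deliberately not computed; npde ([compute_npde()]) is the
#' recommended simulation-based alternative.
#'
#' @param data Long-format observations (as for [map_fit()]).
#' @param pop A [drv_parameters()] object.
#' @param method MAP fitting path passed to [map_fit()].
#' @return Tibble with one row per observation, in `(id, rep, tad)` order:
#'   input columns plus `pred`, `ipred`, `iwres`.
#' @examples
#' pop <- drv_parameters()
#' val <- sample_validation_like(pop, n_subjects = 10, seed = 4)
#' gof_table(val, pop)
#' @export
gof_table <- function(data, pop, method = "batch") {
  data <- dplyr::arrange(as_tibble(data), .data$id, .data$rep, .data$tad)
  popp <- predict_concentration(
    dplyr::select(data, -dplyr::any_of(c("cl", "v", "ka", "cpred"))), pop)
  fits <- map_fit(data, pop, method = method)
  m <- match(paste(data$id, data$rep), paste(fits$id, fits$rep))
  ipred <- css_concentration(data$tad, fits$cl_hat[m], fits$v_hat[m],
                             fits$ka_hat[m], data$dose, data$tau)
  g <- ipred^2 * pop$sigma_exp^2 + pop$sigma_add^2
  out <- data
  out$pred <- popp$cpred
  out$ipred <- ipred
  out$iwres <- (data$dv - ipred) / sqrt(g)
  out
}
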