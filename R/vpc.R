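# Prediction-corrected visual predictive check.

#' Prediction-corrected visual predictive check
#'
#' Observations are binned by time-after-dose quantiles (8 bins by
#' default; bins with fewer than 3 observations are merged with their
#' neighbor).  Each observed and simulated concentration is
#' prediction-corrected: multiplied by the ratio of the bin median
#' population prediction to its own population prediction (predictions at
#' `eta = 0` with the subject's covariates).  Per bin, the 5th, 50th and
#' 95th percentiles of the corrected observations are compared with the
#' distribution of the same percentiles across `K` simulated replicate
#' datasets (2.5-97.5% confidence bands).
#'
#' @inheritParams compute_npde
#' @param n_bins Number of time-after-dose quantile bins (>= 2).
#' @return A `vpc_table`: per-bin tibble with `tad_lo`, `tad_hi`,
#'   `tad_mid`, `n`, observed percentiles `obs_p5`, `obs_p50`, `obs_p95`,
#'   and for each simulated percentile its band `sim_p*_lo`, `sim_p*_md`,
#'   `sim_p*_hi`; the corrected observations are attached as `points`.
#' @examples
#' pop <- drv_parameters()
#' val <- sample_validation_like(pop, n_subjects = 60, seed = 8)
#' vpc <- pc_vpc(val, pop, K = 150, n_bins = 4, seed = 8)
#' vpc$table
#' @export
pc_vpc <- function(data, pop, K = 1000, n_bins = 8, seed = 1) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  data <- dplyr::arrange(as_tibble(data), .data$id, .data$tad)
  if (!nrow(data)) abort("`data` is empty.")
  pred <- predict_concentration(
    dplyr::select(data, -dplyr::any_of(c("cl", "v", "ka", "cpred"))), pop)
  pred0 <- pred$cpred
  # quantile bins on TAD, then merge small bins with their left neighbor
  br <- unique(quantile(data$tad, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(data$tad, br, include.lowest = TRUE, labels = FALSE)
  repeat {
    cnt <- tabulate(bin, nbins = max(bin))
    small <- which(cnt > 0 & cnt < 3)
    if (!length(small) || max(bin) == 1) break
    s <- small[1]
    target <- if (s == 1) min(setdiff(unique(bin), 1)) else
      max(unique(bin)[unique(bin) < s])
    rlang::inform(sprintf("VPC bin %d has %d observation(s); merged with bin %d.",
                          s, cnt[s], target))
    bin[bin == s] <- target
  }
  bin <- match(bin, sort(unique(bin)))  # re-index 1..B
  B <- max(bin)
  bin_med <- vapply(seq_len(B), function(b) median(pred0[bin == b]), 0)
  corr <- bin_med[bin] / pred0
  obs_pc <- data$dv * corr
  sims <- simulate_reference(data, pop, K, seed) * corr
  pct <- function(x) quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  obs_q <- t(vapply(seq_len(B), function(b) pct(obs_pc[bin == b]),
                    numeric(3)))
  # percentile of each bin in each simulated replicate -> band across K
  rows <- lapply(seq_len(B), function(b) {
    qs <- apply(sims[bin == b, , drop = FALSE], 2, pct)  # 3 x K
    band <- t(apply(qs, 1, quantile, c(0.025, 0.5, 0.975), names = FALSE))
    tibble(
      bin = b,
      tad_lo = min(data$tad[bin == b]), tad_hi = max(data$tad[bin == b]),
      tad_mid = median(data$tad[bin == b]), n = sum(bin == b),
      obs_p5 = obs_q[b, 1], obs_p50 = obs_q[b, 2], obs_p95 = obs_q[b, 3],
      sim_p5_lo = band[1, 1], sim_p5_md = band[1, 2], sim_p5_hi = band[1, 3],
      sim_p50_lo = band[2, 1], sim_p50_md = band[2, 2],
      sim_p50_hi = band[2, 3],
      sim_p95_lo = band[3, 1], sim_p95_md = band[3, 2],
      sim_p95_hi = band[3, 3]
    )
  })
  points <- tibble(id = data$id, tad = data$tad, bin = bin,
                   dv_pc = obs_pc)
  structure(list(table = dplyr::bind_rows(rows), points = points, K = K),
            class = "vpc_table")
}

#' @export
print.vpc_table <- function(x, ...) {
  cat(sprintf("<vpc_table> %d bins, K = %d simulations\n",
              nrow(x$table), x$K))
  print(dplyr::select(x$table, "bin", "tad_lo", "tad_hi", "n",
                      "obs_p5", "obs_p50", "obs_p95"))
  invisible(x)
}

#' @export
tidy.vpc_table <- function(x, ...) x$table

#' Plot a prediction-corrected visual predictive check
#'
#' @param object A `vpc_table`.
#' @param ... Unused.
#' @return A ggplot: simulated percentile confidence ribbons, simulated
#'   medians (lines), observed percentiles (points/lines) and the
#'   prediction-corrected observations.
#' @export
autoplot.vpc_table <- function(object, ...) {
  tb <- object$table
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$tad_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p5_lo,
                                      ymax = .data$sim_p5_hi),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p50_lo,
                                      ymax = .data$sim_p50_hi),
                         alpha = 0.2, fill = "firebrick") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p95_lo,
                                      ymax = .data$sim_p95_hi),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p50_md),
                       color = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), linetype = 2) +
    ggplot2::geom_point(data = object$points,
                        ggplot2::aes(x = .data$tad, y = .data$dv_pc),
                        alpha = 0.3, size = 0.7) +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (mg/L)")
}
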