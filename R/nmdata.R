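# NONMEM-style CSV persistence for simulated datasets.
# Header: ID, REP, TAD, DV, CPRED, AMT, II, SEX, CYP3A5, SLCO3A1,
# CL, V, KA, AUC24; missing numeric values are written as ".".

nm_map <- c(ID = "id", REP = "rep", TAD = "tad", DV = "dv", CPRED = "cpred",
            AMT = "dose", II = "tau", SEX = "female", CYP3A5 = "cyp3a5_flag",
            SLCO3A1 = "slco3a1_flag", CL = "cl", V = "v", KA = "ka",
            AUC24 = "auc24_true")

#' Write or read a simulated dataset as NONMEM-style CSV
#'
#' Columns are `ID, REP, TAD, DV, CPRED, AMT, II, SEX, CYP3A5, SLCO3A1, CL,
#' V, KA, AUC24` (`AMT` = dose per administration, `II` = dosing interval,
#' `SEX` = 1 for women, genotype columns are the model's 0/1 indicator
#' flags).  Missing numeric values are written as `"."`.  The round trip is
#' lossless (numbers are written with full precision).
#'
#' @param data Tibble from [simulate_profiles()] or
#'   [sample_validation_like()].
#' @param path CSV file path.
#' @return `write_nmdata()` returns `path` invisibly; `read_nmdata()`
#'   returns a tibble with the package-native column names (`id`, `rep`,
#'   `tad`, `dv`, `cpred`, `dose`, `tau`, `female`, `cyp3a5_flag`,
#'   `slco3a1_flag`, `cl`, `v`, `ka`, `auc24_true`).
#' @examples
#' subj <- sample_covariates(3, seed = 1)
#' sim <- simulate_profiles(subj, drv_parameters(), 1, c(1, 4), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_nmdata(sim, f)
#' read_nmdata(f)
#' @export
write_nmdata <- function(data, path) {
  missing <- setdiff(unname(nm_map), names(data))
  if (length(missing)) {
    abort(paste0("`data` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(setNames(data[unname(nm_map)], names(nm_map)))
  readr::write_csv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_nmdata
#' @export
read_nmdata <- function(path) {
  raw <- readr::read_csv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  missing <- setdiff(names(nm_map), names(raw))
  if (length(missing)) {
    abort(paste0("File lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- setNames(raw[names(nm_map)], unname(nm_map))
  out$id <- as.integer(out$id)
  out$rep <- as.integer(out$rep)
  for (nm in c("female", "cyp3a5_flag", "slco3a1_flag")) {
    out[[nm]] <- as.integer(out[[nm]])
  }
  as_tibble(out)
}
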