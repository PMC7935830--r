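#' Population pharmacokinetic parameters for darunavir
#'
#' Container for the fixed effects, inter-individual variability (IIV)
#' standard deviations and residual-error standard deviations of the
#' one-compartment darunavir model.  The defaults are the published
#' learning-set estimates of the reduced (no alpha-1-acid-glycoprotein)
#' model; any field can be overridden.
#'
#' Fixed effects are apparent oral parameters (bioavailability is absorbed
#' into CL/F and V/F).  Covariate effects are proportional: clearance is
#' multiplied by `(1 + theta_sex)` for women and `(1 + theta_cyp3a5)` for
#' CYP3A5 non-expressers (*3/*3), volume by `(1 + theta_slco3a1)` for
#' SLCO3A1 rs8027174 T-allele carriers.  IIV is log-normal with standard
#' deviations `omega_*`; residual error is exponential (log-normal,
#' `sigma_exp`) plus additive (`sigma_add`, mg/L).
#'
#' @param cl_pop Typical apparent clearance CL/F (L/h).
#' @param v_pop Typical apparent volume V/F (L).
#' @param ka_pop Typical first-order absorption rate constant (1/h).
#' @param theta_sex Proportional effect of female sex on CL.
#' @param theta_cyp3a5 Proportional effect of the CYP3A5 flag on CL.
#' @param theta_slco3a1 Proportional effect of the SLCO3A1 flag on V.
#' @param omega_cl,omega_v,omega_ka IIV standard deviations (log scale).
#' @param sigma_exp Exponential residual standard deviation (log scale).
#' @param sigma_add Additive residual standard deviation (mg/L).
#'
#' @return An object of class `pk_parameters` (a named list).
#' @examples
#' pop <- drv_parameters()
#' pop$cl_pop
#' drv_parameters(omega_ka = 0) # switch off IIV on ka
#' @export
drv_parameters <- function(cl_pop = 12.6, v_pop = 137, ka_pop = 0.545,
                           theta_sex = -0.198, theta_cyp3a5 = -0.192,
                           theta_slco3a1 = 0.991,
                           omega_cl = 0.238, omega_v = 0.353,
                           omega_ka = 0.575,
                           sigma_exp = 0.306, sigma_add = 0.611) {
  pop <- list(
    cl_pop = cl_pop, v_pop = v_pop, ka_pop = ka_pop,
    theta_sex = theta_sex, theta_cyp3a5 = theta_cyp3a5,
    theta_slco3a1 = theta_slco3a1,
    omega_cl = omega_cl, omega_v = omega_v, omega_ka = omega_ka,
    sigma_exp = sigma_exp, sigma_add = sigma_add
  )
  validate_parameters(pop)
}

validate_parameters <- function(pop) {
  needed <- c("cl_pop", "v_pop", "ka_pop", "theta_sex", "theta_cyp3a5",
              "theta_slco3a1", "omega_cl", "omega_v", "omega_ka",
              "sigma_exp", "sigma_add")
  missing <- setdiff(needed, names(pop))
  if (length(missing)) {
    abort(paste0("Parameter set is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  pop <- lapply(pop[needed], as.numeric)
  for (nm in c("cl_pop", "v_pop", "ka_pop")) {
    check_number(pop[[nm]], nm, lower = 1e-12)
  }
  for (nm in c("omega_cl", "omega_v", "omega_ka", "sigma_exp", "sigma_add")) {
    check_number(pop[[nm]], nm, lower = 0)
  }
  for (nm in c("theta_sex", "theta_cyp3a5", "theta_slco3a1")) {
    check_number(pop[[nm]], nm)
    if (1 + pop[[nm]] <= 0) {
      abort(sprintf("`%s` = %g would make a covariate factor non-positive.",
                    nm, pop[[nm]]))
    }
  }
  structure(pop, class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters> one-compartment oral model, steady state\n")
  cat(sprintf("  CL/F %.4g L/h (omega %.3g)   V/F %.4g L (omega %.3g)   ka %.4g 1/h (omega %.3g)\n",
              x$cl_pop, x$omega_cl, x$v_pop, x$omega_v, x$ka_pop, x$omega_ka))
  cat(sprintf("  theta: sex on CL %+.3g, CYP3A5 on CL %+.3g, SLCO3A1 on V %+.3g\n",
              x$theta_sex, x$theta_cyp3a5, x$theta_slco3a1))
  cat(sprintf("  residual: exponential sd %.3g, additive sd %.3g mg/L\n",
              x$sigma_exp, x$sigma_add))
  invisible(x)
}

#' Read or write a parameter set as YAML or JSON
#'
#' Parameter sets are persisted as flat key-value maps using the field names
#' of [drv_parameters()].  The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @param pop A `pk_parameters` object.
#' @return `read_parameters()` returns a `pk_parameters` object;
#'   `write_parameters()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_parameters(drv_parameters(), f)
#' read_parameters(f)
#' @export
read_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(sprintf("Unsupported parameter-file extension '%s'.", ext))
  )
  validate_parameters(as.list(raw))
}

#' @rdname read_parameters
#' @export
write_parameters <- function(pop, path) {
  pop <- validate_parameters(unclass(pop))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(unclass(pop), path),
    json = jsonlite::write_json(unclass(pop), path,
                                auto_unbox = TRUE, digits = NA),
    abort(sprintf("Unsupported parameter-file extension '%s'.", ext))
  )
  invisible(path)
}
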