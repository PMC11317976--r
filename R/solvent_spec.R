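#' Solvent-level parameters of the CCSA method
#'
#' A \code{solvent_spec} collects every solvent-level constant the hybrid
#' cluster-continuum machinery needs: the damping-function constants
#' (\code{W_R}, \code{eta}, \code{E_R}), the cluster-integral surrogate
#' \code{gamma_N}, the continuum surface tension \code{alpha_A}, the solvent
#' probe radius, the neat-solvent concentration term RT ln[S], the solvent's
#' own solvation free energy, and the single-ion proton anchor that fixes the
#' absolute scale of the thermodynamic cycles.
#'
#' @param name Solvent name.
#' @param temperature Absolute temperature, K.
#' @param probe_radius Solvent probe radius R_solv, Angstrom.
#' @param alpha_A Surface tension, kcal mol^-1 Bohr^-2 (negative when fitted
#'   to attractive nonelectrostatic solvation).
#' @param gamma_N Positive constant standing in for the configuration
#'   integral of the cluster expansion, kcal mol^-1.
#' @param W_R Damping reference for the potential of mean force, kcal mol^-1
#'   (negative).
#' @param eta Dimensionless damping exponent (> 0).
#' @param E_R Damping reference for the gas-phase interaction energy,
#'   kcal mol^-1; must be more negative than \code{W_R}.
#' @param rt_ln_conc RT ln[S] for the neat solvent, kcal mol^-1.
#' @param dG_solv_solvent Solvation free energy of the solvent in itself,
#'   kcal mol^-1 (1 M gas / 1 M solution standard states).
#' @param proton_solvation_anchor Assumed single-ion solvation free energy of
#'   the proton on the working scale, kcal mol^-1.
#' @return An object of class \code{solvent_spec} (a named list).
#' @examples
#' spec <- acetonitrile_spec()
#' spec$gamma_N
#' @export
solvent_spec <- function(name,
                         temperature = 298.15,
                         probe_radius,
                         alpha_A,
                         gamma_N,
                         W_R,
                         eta,
                         E_R,
                         rt_ln_conc,
                         dG_solv_solvent = NA_real_,
                         proton_solvation_anchor = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L) {
      stop(sprintf("'%s' must be a single numeric value", what), call. = FALSE)
    }
    as.numeric(x)
  }
  spec <- list(
    name = name,
    temperature = num1(temperature, "temperature"),
    probe_radius = num1(probe_radius, "probe_radius"),
    alpha_A = num1(alpha_A, "alpha_A"),
    gamma_N = num1(gamma_N, "gamma_N"),
    W_R = num1(W_R, "W_R"),
    eta = num1(eta, "eta"),
    E_R = num1(E_R, "E_R"),
    rt_ln_conc = num1(rt_ln_conc, "rt_ln_conc"),
    dG_solv_solvent = num1(dG_solv_solvent, "dG_solv_solvent"),
    proton_solvation_anchor = num1(proton_solvation_anchor,
                                   "proton_solvation_anchor")
  )
  if (spec$temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (spec$probe_radius <= 0) stop("probe_radius must be > 0", call. = FALSE)
  if (spec$gamma_N < 0) stop("gamma_N must be >= 0", call. = FALSE)
  if (spec$W_R >= 0) stop("W_R must be negative", call. = FALSE)
  if (spec$E_R >= spec$W_R) stop("E_R must be more negative than W_R",
                                 call. = FALSE)
  if (spec$eta <= 0) stop("eta must be > 0", call. = FALSE)
  structure(spec, class = "solvent_spec")
}

#' Packaged acetonitrile parameterization
#'
#' The published acetonitrile parameter set: gamma_N = 1.0, W_R = -2,
#' eta = 3/2, E_R = -12 kcal/mol, alpha_A = -0.00531 kcal/Bohr^2,
#' R_solv = 2.49 Angstrom, RT ln[CH3CN] = 1.75 kcal/mol,
#' dG*_solv(CH3CN) = -4.19 kcal/mol and a proton anchor of -253.2 kcal/mol
#' (surface potential excluded).
#'
#' @return A \code{solvent_spec}.
#' @export
acetonitrile_spec <- function() {
  solvent_spec(
    name = "acetonitrile",
    temperature = 298.15,
    probe_radius = 2.49,
    alpha_A = -0.00531,
    gamma_N = 1.0,
    W_R = -2.0,
    eta = 1.5,
    E_R = -12.0,
    rt_ln_conc = 1.75,
    dG_solv_solvent = -4.19,
    proton_solvation_anchor = -253.2
  )
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf("<solvent_spec> %s (T = %.2f K)\n", x$name, x$temperature))
  flds <- setdiff(names(x), c("name", "temperature"))
  for (f in flds) cat(sprintf("  %-24s %g\n", f, x[[f]]))
  invisible(x)
}

#' Read or write a solvent specification as JSON
#'
#' @param path File path.
#' @return \code{read_solvent_spec} returns a \code{solvent_spec};
#'   \code{write_solvent_spec} returns \code{path} invisibly.
#' @export
read_solvent_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(solvent_spec, raw)
}

#' @rdname read_solvent_spec
#' @param spec A \code{solvent_spec}.
#' @export
write_solvent_spec <- function(spec, path) {
  stopifnot(inherits(spec, "solvent_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
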