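# Benchmark error statistics in the conventions the solvation literature
# uses for this data set: signed error = calculated - experimental, SD-MSE
# with the sample (n-1) denominator, and R^2 the squared Pearson correlation
# of calculated against experimental values.

#' Aligned calculated/experimental benchmark table
#'
#' @param ids Species labels.
#' @param calc Calculated solvation free energies, kcal mol^-1.
#' @param exp Experimental reference values, kcal mol^-1.
#' @return A data frame of class \code{benchmark_table} with an
#'   \code{error = calc - exp} column.
#' @export
benchmark_table <- function(ids, calc, exp) {
  if (length(calc) != length(exp) || length(ids) != length(calc)) {
    stop("ids, calc and exp must have equal length", call. = FALSE)
  }
  if (length(calc) < 2L) stop("need at least 2 species", call. = FALSE)
  if (any(!is.finite(calc)) || any(!is.finite(exp))) {
    stop("calc and exp must be finite after alignment", call. = FALSE)
  }
  structure(data.frame(id = as.character(ids), calc = calc, exp = exp,
                       error = calc - exp, stringsAsFactors = FALSE),
            class = c("benchmark_table", "data.frame"))
}

#' Error statistics of a benchmark
#'
#' Returns the mean signed error (MSE), its sample standard deviation
#' (SD-MSE, n-1 denominator — the convention that reproduces the published
#' (RMSE, MSE, SD-MSE) triples of this benchmark), the RMSE, the mean
#' unsigned error (MUE) and R^2 as the squared Pearson correlation between
#' calculated and experimental values. SD-MSE measures relative accuracy: it
#' is blind to a constant offset such as a shifted proton scale, which is
#' why it is the headline number for reaction-level performance.
#'
#' @param table A \code{\link{benchmark_table}}.
#' @return A list of class \code{error_stats}: \code{n}, \code{MSE},
#'   \code{SD_MSE}, \code{RMSE}, \code{MUE}, \code{R2}.
#' @export
error_stats <- function(table) {
  stopifnot(inherits(table, "benchmark_table"))
  e <- table$error
  n <- length(e)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)
  r2 <- if (stats::sd(table$calc) == 0 || stats::sd(table$exp) == 0) {
    NA_real_
  } else {
    stats::cor(table$calc, table$exp)^2
  }
  structure(list(
    n = n,
    MSE = mean(e),
    SD_MSE = stats::sd(e),
    RMSE = sqrt(mean(e^2)),
    MUE = mean(abs(e)),
    R2 = r2
  ), class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  MSE = %.2f  SD-MSE = %.2f  RMSE = %.2f  MUE = %.2f  R2 = %s\n",
    x$n, x$MSE, x$SD_MSE, x$RMSE, x$MUE,
    if (is.na(x$R2)) "NA" else sprintf("%.2f", x$R2)))
  invisible(x)
}

#' SD-MSE from a published (RMSE, MSE, n) triple
#'
#' Inverts the variance identity \code{RMSE^2 = MSE^2 + SD^2 (n-1)/n} to
#' recover the sample standard deviation of the signed errors. Used to pin
#' the n-1 convention against published statistics.
#'
#' @param rmse Root-mean-square error, kcal mol^-1.
#' @param mse Mean signed error, kcal mol^-1.
#' @param n Number of species.
#' @return SD-MSE, kcal mol^-1.
#' @export
sd_mse_from_identity <- function(rmse, mse, n) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  v <- (rmse^2 - mse^2) * n / (n - 1)
  if (v < 0) stop("inconsistent triple: RMSE < |MSE|", call. = FALSE)
  sqrt(v)
}

#' Fit the surface tension alpha_A to reference solvation data
#'
#' Least-squares slope, through the origin, of the nonelectrostatic residual
#' \code{dG_exp - dG_elec} against molecular area: the single-parameter fit
#' that defines the continuum baseline's surface-tension term. The surface
#' tension is tied to the surface definition it was fitted against, so
#' refitting against areas from this package's union-of-spheres surface is
#' the supported route to a consistent (surface, alpha_A) pair.
#'
#' @param areas Molecular areas, Bohr^2.
#' @param dG_elec Electrostatic continuum contributions, kcal mol^-1.
#' @param dG_exp Experimental solvation free energies, kcal mol^-1.
#' @return A list of class \code{alpha_fit}: \code{alpha_A}, \code{se}
#'   (standard error of the slope), \code{residual_sd}, \code{n},
#'   \code{residuals}.
#' @export
fit_surface_tension <- function(areas, dG_elec, dG_exp) {
  n <- length(areas)
  if (n < 2L || length(dG_elec) != n || length(dG_exp) != n) {
    stop("need >= 2 species with matching areas, dG_elec, dG_exp",
         call. = FALSE)
  }
  if (all(areas == areas[1])) stop("degenerate design: all areas equal",
                                   call. = FALSE)
  y <- dG_exp - dG_elec
  # through-origin OLS in closed form (df = n - 1)
  sxx <- sum(areas^2)
  alpha <- sum(areas * y) / sxx
  r <- y - alpha * areas
  residual_sd <- sqrt(sum(r^2) / (n - 1))
  structure(list(alpha_A = alpha,
                 se = residual_sd / sqrt(sxx),
                 residual_sd = residual_sd,
                 n = n,
                 residuals = r),
            class = "alpha_fit")
}

#' Generate a synthetic benchmark with known parameters
#'
#' Emulates the structure (not the chemistry) of the acetonitrile benchmark
#' tables: molecular areas uniform on [250, 900] Bohr^2 and electrostatic
#' terms uniform on [-12, -1] kcal/mol (neutral organic-solute scale), a
#' true surface tension \code{alpha_true}, experimental values
#' \code{dG_elec + alpha_true * area + noise}, and explicit-solvent
#' descriptors spanning the cation table's spread: dW uniform on [-21, 0]
#' and dE = 2 dW + U(-8, -4) clamped to [-41, -8]. Gaussian noise with
#' standard deviation \code{noise_sd} models experimental scatter.
#'
#' @param n Number of species (>= 2).
#' @param alpha_true True surface tension, kcal mol^-1 Bohr^-2.
#' @param noise_sd Gaussian noise SD on the reference values, kcal mol^-1
#'   (>= 0).
#' @param seed Integer RNG seed (required, for reproducibility).
#' @return A species table (class \code{ccsa_species}) with additional
#'   columns \code{dG_exp} and \code{dG_cont} assembled from the components.
#' @export
synthesize_benchmark <- function(n, alpha_true, noise_sd, seed) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (missing(seed) || !is.finite(seed)) stop("seed is required",
                                              call. = FALSE)
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(as.integer(seed))
  area <- stats::runif(n, 250, 900)
  dG_elec <- stats::runif(n, -12, -1)
  dW <- stats::runif(n, -21, 0)
  dE <- pmin(pmax(2 * dW + stats::runif(n, -8, -4), -41), -8)
  dG_exp <- dG_elec + alpha_true * area + stats::rnorm(n, 0, noise_sd)
  tab <- data.frame(id = sprintf("syn%02d", seq_len(n)), charge = 0L,
                    dG_cont = dG_elec + alpha_true * area,
                    dG_elec = dG_elec, area = area, dW = dW, dE = dE,
                    dG_exp = dG_exp, stringsAsFactors = FALSE)
  validate_species(tab)
  class(tab) <- c("ccsa_species", "data.frame")
  tab
}
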