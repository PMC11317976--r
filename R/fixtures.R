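#' Packaged benchmark fixtures
#'
#' Three transcribed reference sets ship with the package:
#' \describe{
#'   \item{\code{table1}}{The 22-cation acetonitrile benchmark: CPCM-A
#'     continuum solvation free energy, potential of mean force dW, gas-phase
#'     interaction energy dE, and (as annotations) the published damping
#'     factor and final CCSA value for each cation BH1..BH22.}
#'   \item{\code{table2}}{Three proton-transfer reactions with electronic
#'     energy, thermal (vib/rot/trans) correction, solvation variation under
#'     each of the three models, the assembled solution-phase free energies,
#'     and the pKa-derived experimental value.}
#'   \item{\code{constants}}{The acetonitrile \code{\link{solvent_spec}}.}
#' }
#' All energies are kcal mol^-1 at 298 K.
#'
#' @param name One of \code{"table1"}, \code{"table2"}, \code{"constants"}.
#' @return \code{table1}: a \code{ccsa_species} table; \code{table2}: a data
#'   frame of reactions; \code{constants}: a \code{solvent_spec}.
#' @examples
#' tab1 <- builtin_fixture("table1")
#' subset(tab1, id == "BH18")$dW
#' @export
builtin_fixture <- function(name = c("table1", "table2", "constants")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "ccsa",
                                  mustWork = TRUE)
  switch(name,
    table1 = load_species_table(path("table1_cations.csv")),
    table2 = utils::read.csv(path("table2_reactions.csv"),
                             stringsAsFactors = FALSE, check.names = FALSE),
    constants = read_solvent_spec(path("acetonitrile.json"))
  )
}
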