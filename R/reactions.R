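# Solution-phase reaction free energies: Delta G_sol = Delta E_elec +
# Delta G_vrt + Delta Delta G_solv, with the solvation variation assembled
# per model and the explicit-solvent bookkeeping checked (at most one
# explicit solvent molecule per side, balanced across sides under CCSA).

#' Describe a reaction for free-energy assembly
#'
#' @param reactants,products Named integer vectors of stoichiometric counts,
#'   names being species ids (e.g. \code{c(PhCOOH = 1, MeOH = 1)}).
#' @param explicit_solvent Integer vector \code{c(reactants = , products =)}
#'   counting explicit solvent molecules carried on each side (0 or 1).
#' @param label Optional display label.
#' @return An object of class \code{reaction_spec}.
#' @export
reaction_spec <- function(reactants, products,
                          explicit_solvent = c(reactants = 0L, products = 0L),
                          label = NULL) {
  chk <- function(side, what) {
    if (is.null(names(side)) || any(!nzchar(names(side)))) {
      stop(what, " must be a named vector of counts", call. = FALSE)
    }
    if (any(side < 1)) stop(what, " counts must be >= 1", call. = FALSE)
    storage.mode(side) <- "integer"
    side
  }
  reactants <- chk(reactants, "reactants")
  products <- chk(products, "products")
  explicit_solvent <- c(reactants = as.integer(explicit_solvent[["reactants"]]),
                        products = as.integer(explicit_solvent[["products"]]))
  structure(list(reactants = reactants, products = products,
                 explicit_solvent = explicit_solvent,
                 label = label %||%
                   paste(paste(names(reactants), collapse = " + "), "->",
                         paste(paste(names(products), collapse = " + ")))),
            class = "reaction_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solution-phase free energy of reaction
#'
#' \deqn{\Delta G_{sol} = \Delta E_{elec} + \Delta G_{vrt} +
#'   \Delta\Delta G_{solv}}
#' with the electronic-energy and thermal differences taken in the gas phase
#' and the solvation variation from any of the three solvation models.
#'
#' @param dE_elec Electronic reaction energy, kcal mol^-1.
#' @param dG_vrt Vibrational/rotational/translational free-energy
#'   difference, kcal mol^-1.
#' @param ddG_solv Solvation free-energy variation, kcal mol^-1.
#' @return Reaction free energy in solution, kcal mol^-1.
#' @export
reaction_free_energy <- function(dE_elec, dG_vrt, ddG_solv) {
  vals <- c(dE_elec, dG_vrt, ddG_solv)
  if (any(!is.finite(vals))) stop("all components must be finite",
                                  call. = FALSE)
  dE_elec + dG_vrt + ddG_solv
}

#' Solvation free-energy variation of a reaction
#'
#' Stoichiometric sum over products minus reactants of per-species solvation
#' free energies under the chosen model.
#'
#' @param rxn A \code{\link{reaction_spec}}.
#' @param solvation Named numeric vector (or one-column lookup) of per-
#'   species solvation free energies, kcal mol^-1, under one model.
#' @return Delta Delta G_solv, kcal mol^-1.
#' @export
ddG_solv_for_reaction <- function(rxn, solvation) {
  stopifnot(inherits(rxn, "reaction_spec"))
  side_sum <- function(side) {
    miss <- setdiff(names(side), names(solvation))
    if (length(miss)) {
      stop("no solvation value for species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    sum(side * solvation[names(side)])
  }
  side_sum(rxn$products) - side_sum(rxn$reactants)
}

#' Check the explicit-solvent bookkeeping of a reaction
#'
#' Under the hybrid cluster-continuum treatment at most one explicit solvent
#' molecule may ride on each side of the chemical equation, and under CCSA
#' the two sides must carry the same number so the explicit contribution
#' cancels consistently.
#'
#' @param rxn A \code{\link{reaction_spec}}.
#' @param model \code{"continuum"}, \code{"ccsa"} or \code{"ccqc"}.
#' @return A list with \code{ok} (logical) and \code{violations} (character
#'   vector of human-readable findings, empty when ok).
#' @export
check_explicit_solvent_balance <- function(rxn,
                                           model = c("ccsa", "continuum",
                                                     "ccqc")) {
  stopifnot(inherits(rxn, "reaction_spec"))
  model <- match.arg(model)
  es <- rxn$explicit_solvent
  v <- character(0)
  for (side in names(es)) {
    if (es[[side]] > 1L) {
      v <- c(v, sprintf("%s side carries %d explicit solvent molecules (max 1)",
                        side, es[[side]]))
    }
  }
  if (model == "ccsa" && es[["reactants"]] != es[["products"]]) {
    v <- c(v, sprintf(
      "explicit solvent unbalanced under CCSA: %d reactant-side vs %d product-side",
      es[["reactants"]], es[["products"]]))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Load reactions from a JSON document plus a species-values CSV
#'
#' The JSON document is a list of objects with fields \code{label},
#' \code{reactants} / \code{products} (objects mapping species id to count),
#' and optional \code{explicit_solvent} (\code{{"reactants": 0, "products":
#' 1}}). The CSV must have an \code{id} column and one column per solvation
#' model holding per-species values in kcal/mol.
#'
#' @param path JSON file path.
#' @return A list of \code{\link{reaction_spec}} objects.
#' @export
load_reactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc, function(r) {
    es <- r$explicit_solvent %||% list(reactants = 0L, products = 0L)
    reaction_spec(
      reactants = unlist(r$reactants),
      products = unlist(r$products),
      explicit_solvent = c(reactants = as.integer(es$reactants),
                           products = as.integer(es$products)),
      label = r$label %||% NULL
    )
  })
}
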