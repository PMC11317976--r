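#' Create a single species record
#'
#' A species record carries everything the solvation engines need for one
#' solute: its continuum solvation free energy \code{dG_cont} (or the
#' components \code{dG_elec} + \code{area} from which the CPCM-A total is
#' assembled), the potential of mean force \code{dW} for attaching one
#' explicit solvent molecule (A + S -> AS), and the gas-phase solute-solvent
#' interaction energy \code{dE} that gates the second damping term. All
#' energies are kcal mol^-1; areas are Bohr^2.
#'
#' @param id Species label (e.g. "BH1", "A7").
#' @param charge Integer formal charge.
#' @param dG_cont Continuum solvation free energy, kcal mol^-1, or NA when
#'   supplied as components.
#' @param dG_elec Electrostatic continuum part, kcal mol^-1 (optional).
#' @param area Molecular surface area, Bohr^2 (optional, pairs with
#'   \code{dG_elec}).
#' @param dW Potential of mean force for A + S -> AS, kcal mol^-1, or NA.
#' @param dE Gas-phase interaction energy of the AS complex, kcal mol^-1, or
#'   NA. May only be present when \code{dW} is present.
#' @param ... Further named scalar annotations, preserved verbatim.
#' @return A one-row data frame of class \code{ccsa_species}.
#' @export
species_record <- function(id, charge = 0L, dG_cont = NA_real_,
                           dG_elec = NA_real_, area = NA_real_,
                           dW = NA_real_, dE = NA_real_, ...) {
  rec <- data.frame(id = as.character(id), charge = as.integer(charge),
                    dG_cont = as.numeric(dG_cont),
                    dG_elec = as.numeric(dG_elec), area = as.numeric(area),
                    dW = as.numeric(dW), dE = as.numeric(dE),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) rec[[nm]] <- extra[[nm]]
  validate_species(rec)
  class(rec) <- c("ccsa_species", "data.frame")
  rec
}

#' Validate a species table against the record invariants
#'
#' Checks, row by row, that either \code{dG_cont} or the pair
#' (\code{dG_elec}, \code{area}) is present, and that \code{dE} never appears
#' without \code{dW} (the explicit-solvent correction is skipped as a whole,
#' never half-specified).
#'
#' @param tab A data frame of species records.
#' @return \code{tab}, invisibly, if valid; otherwise an error naming the
#'   offending row and field.
#' @export
validate_species <- function(tab) {
  need <- c("id", "dG_cont", "dG_elec", "area", "dW", "dE")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("species table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    has_cont <- is.finite(tab$dG_cont[i])
    has_comp <- is.finite(tab$dG_elec[i]) && is.finite(tab$area[i])
    if (!has_cont && !has_comp) {
      stop(sprintf(
        "row %d (%s): needs dG_cont or the pair dG_elec + area", i, id),
        call. = FALSE)
    }
    if (is.finite(tab$dE[i]) && !is.finite(tab$dW[i])) {
      stop(sprintf("row %d (%s): dE present but dW missing", i, id),
           call. = FALSE)
    }
  }
  invisible(tab)
}

#' Resolve the continuum solvation free energy of a record
#'
#' Returns \code{dG_cont} when stored directly, otherwise assembles the
#' CPCM-A total \code{dG_elec + alpha_A * area} from components.
#'
#' @param rec One row of a species table.
#' @param spec A \code{\link{solvent_spec}} (supplies \code{alpha_A}).
#' @return Continuum solvation free energy, kcal mol^-1.
#' @export
resolve_dG_cont <- function(rec, spec) {
  if (is.finite(rec$dG_cont)) return(as.numeric(rec$dG_cont))
  cpcma_total(rec$dG_elec, rec$area, spec$alpha_A)
}

#' Read a species table from CSV
#'
#' The file is comma-separated, UTF-8, period decimal; the \code{id} column
#' is required. A \code{unit} column, if present, must read \code{kcal/mol}
#' in every row (mixed-unit files are rejected rather than converted).
#' Columns outside the schema are preserved as annotations.
#'
#' @param path CSV file path.
#' @param schema \code{"species"} (default) or \code{"ccqc"}; the latter
#'   requires the complexation columns \code{dG_gas_complexation},
#'   \code{dG_solv_AS}, \code{dG_vrt_AS}.
#' @return A data frame of class \code{ccsa_species} (or a plain validated
#'   data frame for the ccqc schema).
#' @export
load_species_table <- function(path, schema = c("species", "ccqc")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  if (!"id" %in% names(tab)) stop("species file lacks an 'id' column",
                                  call. = FALSE)
  if ("unit" %in% names(tab)) {
    bad <- which(tab$unit != "kcal/mol")
    if (length(bad)) {
      stop(sprintf("row %d (%s): unit '%s' is not kcal/mol",
                   bad[1], tab$id[bad[1]], tab$unit[bad[1]]), call. = FALSE)
    }
  }
  if (schema == "ccqc") {
    need <- c("dG_gas_complexation", "dG_solv_AS", "dG_vrt_AS")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop("ccqc file lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    for (nm in need) {
      bad <- which(!is.finite(tab[[nm]]))
      if (length(bad)) {
        stop(sprintf("row %d (%s): field %s is not a finite number",
                     bad[1], tab$id[bad[1]], nm), call. = FALSE)
      }
    }
    return(tab)
  }
  for (nm in c("charge", "dG_cont", "dG_elec", "area", "dW", "dE")) {
    if (!nm %in% names(tab)) {
      tab[[nm]] <- if (nm == "charge") NA_integer_ else NA_real_
    }
  }
  if (nrow(tab)) validate_species(tab)
  class(tab) <- c("ccsa_species", "data.frame")
  tab
}

#' Write a species table to CSV
#'
#' Numeric fields are written with full precision so that a load/write round
#' trip is bit-identical.
#'
#' @param tab A species table.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_species_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
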