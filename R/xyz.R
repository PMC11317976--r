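#' Molecular geometry
#'
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param radii_override Optional named numeric vector of per-element radii
#'   (Angstrom) taking precedence over the surface spec's radii table.
#' @return An object of class \code{geometry}.
#' @export
geometry <- function(elements, coordinates, radii_override = NULL) {
  coordinates <- as.matrix(coordinates)
  if (!is.numeric(coordinates) || ncol(coordinates) != 3L) {
    stop("coordinates must be an n x 3 numeric matrix", call. = FALSE)
  }
  if (length(elements) != nrow(coordinates)) {
    stop("elements and coordinates disagree in length", call. = FALSE)
  }
  if (any(!is.finite(coordinates))) {
    stop("coordinates contain non-finite values", call. = FALSE)
  }
  elements <- normalize_element(elements)
  dimnames(coordinates) <- list(NULL, c("x", "y", "z"))
  structure(list(elements = elements, coordinates = coordinates,
                 radii_override = radii_override),
            class = "geometry")
}

# "cl"/"CL" -> "Cl"; element symbols are matched case-insensitively.
normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
}

#' Read a geometry from a standard XYZ file
#'
#' Expects the usual dialect: an atom-count line, a comment line, then one
#' \code{element x y z} line per atom (whitespace-separated, Angstrom).
#' Element symbols are normalized case-insensitively; coordinates are kept at
#' full precision.
#'
#' @param path XYZ file path.
#' @return A \code{\link{geometry}}.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ count line is not a positive integer: ", path, call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("XYZ declares %d atoms but has %d atom lines", n,
                 length(body)), call. = FALSE)
  }
  body <- body[seq_len(n)]
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop(sprintf("XYZ atom line %d is malformed: '%s'", i, body[i]),
           call. = FALSE)
    }
    el[i] <- tok[1]
    val <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(val))) {
      stop(sprintf("XYZ atom line %d has unparsable coordinates: '%s'",
                   i, body[i]), call. = FALSE)
    }
    xyz[i, ] <- val
  }
  geometry(el, xyz)
}
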