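# Conformation: a sequence plus per-residue (phi, psi, omega) angles, with
# lazily realized coordinates and a cached energy.

#' Create a conformation
#'
#' @param sequence one-letter residue codes (vector or single string), n >= 1.
#' @param angles n x 3 matrix (phi, psi, omega) in degrees, or a length-3n
#'   vector in residue-major order.
#' @param geometry idealized covalent geometry used when coordinates are
#'   realized.
#' @param generation,parent provenance tags carried through the search.
#' @return An object of class \code{conformation}.
#' @examples
#' conf <- extended_conformation("ACDEFG")
#' conf
#' @export
conformation <- function(sequence, angles, geometry = ideal_geometry(),
                         generation = 0L, parent = NA_integer_) {
  sequence <- .check_sequence(sequence)
  angles <- .check_angles(angles, length(sequence))
  angles[] <- wrap_angle(angles)
  structure(list(sequence = sequence, angles = angles, geometry = geometry,
                 coords = NULL, energy = NULL,
                 generation = generation, parent = parent),
            class = "conformation")
}

#' Extended starting conformation
#'
#' The canonical search start: every stored phi, psi and omega set to 180
#' degrees (fully extended trans chain). The subsequent randomizing fragment
#' replacements erase its details.
#'
#' @inheritParams conformation
#' @return A \code{conformation} with all angles 180.
#' @export
extended_conformation <- function(sequence, geometry = ideal_geometry()) {
  sequence <- .check_sequence(sequence)
  conformation(sequence, matrix(180, length(sequence), 3L), geometry)
}

#' Replace the dihedral angles of a conformation
#'
#' Returns a new conformation with the given angles; coordinate and energy
#' caches are invalidated.
#'
#' @param conf a \code{conformation}.
#' @param angles replacement n x 3 matrix or 3n vector, degrees.
#' @return the updated \code{conformation}.
#' @export
set_angles <- function(conf, angles) {
  stopifnot(inherits(conf, "conformation"))
  angles <- .check_angles(angles, length(conf$sequence))
  conf$angles <- wrap_angle(angles)
  dim(conf$angles) <- c(length(conf$sequence), 3L)
  colnames(conf$angles) <- c("phi", "psi", "omega")
  conf$coords <- NULL
  conf$energy <- NULL
  conf
}

#' Realize cartesian coordinates of a conformation
#'
#' Runs forward kinematics if no cached coordinates are present and returns
#' the conformation with its \code{coords} field filled.
#'
#' @param conf a \code{conformation}.
#' @return the conformation with realized coordinates.
#' @export
realize_coordinates <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  if (is.null(conf$coords))
    conf$coords <- build_coordinates(conf$angles, conf$sequence, conf$geometry)
  conf
}

#' Backbone coordinates of a conformation
#'
#' @param conf a \code{conformation}.
#' @return A \code{backbone_coords} object.
#' @export
coordinates <- function(conf) {
  realize_coordinates(conf)$coords
}

#' CA coordinates of a conformation
#'
#' @param conf a \code{conformation}.
#' @return n x 3 matrix of CA positions (Angstrom).
#' @export
ca_coordinates <- function(conf) {
  if (!is.null(conf$coords)) return(conf$coords$CA)
  .ca_trace(conf$angles, conf$geometry)
}

#' @export
print.conformation <- function(x, ...) {
  n <- length(x$sequence)
  cat("Conformation: ", n, " residues (",
      paste(x$sequence[seq_len(min(10L, n))], collapse = ""),
      if (n > 10L) "..." else "", ")\n", sep = "")
  cat("  generation ", x$generation,
      if (!is.null(x$energy)) paste0(", energy ", signif(x$energy, 6)) else
        ", energy not scored",
      if (!is.null(x$coords)) ", coordinates realized" else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.conformation <- function(x, ...) x$angles
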