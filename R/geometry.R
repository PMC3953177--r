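# Kinematic chain model: idealized covalent geometry, forward kinematics from
# backbone dihedrals (NeRF-style placement), and dihedral measurement.

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# binary hydrophobicity classes used by the burial and water terms
.HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

.DEG <- pi / 180

#' Idealized covalent geometry table
#'
#' Bond lengths (Angstrom) and bond angles (degrees) held fixed for every
#' conformation, so that a chain of n residues is fully specified by its 3n
#' backbone dihedral angles. Defaults are standard idealized backbone values
#' (CHARMM22-derived). The carbonyl O is placed in the peptide plane trans to
#' the following amide nitrogen; Cbeta is placed tetrahedrally from N, CA, C
#' with a fixed improper torsion (L-configuration); glycine carries no Cbeta.
#'
#' @param ... named overrides for any entry of the default table.
#' @return A named list of class \code{ideal_geometry}.
#' @examples
#' g <- ideal_geometry()
#' g$b_n_ca
#' @export
ideal_geometry <- function(...) {
  g <- list(
    b_n_ca  = 1.458,  # N-CA bond
    b_ca_c  = 1.525,  # CA-C bond
    b_c_n   = 1.329,  # C-N peptide bond
    b_c_o   = 1.231,  # C=O bond
    b_ca_cb = 1.530,  # CA-CB bond
    a_n_ca_c  = 111.2,  # N-CA-C
    a_ca_c_n  = 116.2,  # CA-C-N(next)
    a_c_n_ca  = 121.7,  # C(prev)-N-CA
    a_ca_c_o  = 120.8,  # CA-C-O
    a_n_ca_cb = 110.5,  # N-CA-CB
    t_cb      = -122.5  # improper dihedral C-N-CA-CB fixing CB chirality
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(g))
    if (length(bad)) stop("unknown geometry entries: ", paste(bad, collapse = ", "))
    g[names(ov)] <- ov
  }
  structure(g, class = "ideal_geometry")
}

.check_sequence <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) == 1L && nchar(sequence[1L]) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  bad <- which(!(sequence %in% .AA1))
  if (length(bad))
    stop("unknown residue code '", sequence[bad[1L]], "' at position ", bad[1L])
  sequence
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Place atom D given reference atoms a-b-c, the c-D bond length, the b-c-D
# bond angle (deg) and the a-b-c-D dihedral (deg). Natural-extension
# reference frame; the sign convention matches dihedral_angle().
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * .DEG
  ph <- torsion * .DEG
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  nv <- .cross3(ab, bc)
  nv <- nv / sqrt(sum(nv * nv))
  mv <- .cross3(nv, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * mv + d2[3L] * nv
}

#' Dihedral angle of four points
#'
#' Signed dihedral about the b2 = p3 - p2 axis, IUPAC sign convention
#' (trans = 180), in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  y <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2 * b2))
  ang <- atan2(y, sum(n1 * n2)) / .DEG
  wrap_angle(ang)
}

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  idx <- which(w <= -180)
  w[idx] <- w[idx] + 360
  w
}

.check_angles <- function(angles, n) {
  if (is.vector(angles)) angles <- matrix(angles, ncol = 3L, byrow = TRUE)
  if (!is.matrix(angles) || ncol(angles) != 3L)
    stop("angles must be an n x 3 matrix of (phi, psi, omega) in degrees")
  if (nrow(angles) != n)
    stop("angle count ", 3L * nrow(angles), " does not match 3n = ", 3L * n)
  storage.mode(angles) <- "double"
  colnames(angles) <- c("phi", "psi", "omega")
  angles
}

#' Forward kinematics: dihedral angles to backbone coordinates
#'
#' Builds cartesian coordinates for N, CA, C, O and (non-glycine) CB under the
#' idealized-geometry assumption. The first residue is placed in a canonical
#' frame: N at the origin, CA on the +x axis, C in the xy-plane (y > 0).
#' phi of residue 1 and omega of residue 1 are kinematically inert, as is psi
#' of the last residue for the N/CA/C trace (it still orients the terminal
#' carbonyl O).
#'
#' @param angles n x 3 matrix of (phi, psi, omega) in degrees, or a length-3n
#'   vector in residue-major order.
#' @param sequence character vector of one-letter residue codes (or a single
#'   string).
#' @param geometry an \code{\link{ideal_geometry}} table.
#' @return An object of class \code{backbone_coords}: a list with the
#'   sequence and n x 3 coordinate matrices \code{N}, \code{CA}, \code{C},
#'   \code{O}, \code{CB} (rows of \code{CB} are \code{NA} for glycine).
#' @export
build_coordinates <- function(angles, sequence, geometry = ideal_geometry()) {
  sequence <- .check_sequence(sequence)
  n <- length(sequence)
  angles <- .check_angles(angles, n)

  N  <- matrix(NA_real_, n, 3L)
  CA <- matrix(NA_real_, n, 3L)
  Cc <- matrix(NA_real_, n, 3L)

  g <- geometry
  # canonical frame for residue 1
  N[1L, ]  <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * .DEG
  Cc[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(th), sin(th), 0)

  if (n > 1L) {
    for (i in 2L:n) {
      N[i, ] <- .place_atom(N[i - 1L, ], CA[i - 1L, ], Cc[i - 1L, ],
                            g$b_c_n, g$a_ca_c_n, angles[i - 1L, 2L])
      CA[i, ] <- .place_atom(CA[i - 1L, ], Cc[i - 1L, ], N[i, ],
                             g$b_n_ca, g$a_c_n_ca, angles[i, 3L])
      Cc[i, ] <- .place_atom(Cc[i - 1L, ], N[i, ], CA[i, ],
                             g$b_ca_c, g$a_n_ca_c, angles[i, 1L])
    }
  }

  O  <- matrix(NA_real_, n, 3L)
  CB <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    O[i, ] <- .place_atom(N[i, ], CA[i, ], Cc[i, ],
                          g$b_c_o, g$a_ca_c_o, wrap_angle(angles[i, 2L] + 180))
    if (sequence[i] != "G")
      CB[i, ] <- .place_atom(Cc[i, ], N[i, ], CA[i, ],
                             g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
  }

  structure(list(sequence = sequence, N = N, CA = CA, C = Cc, O = O, CB = CB),
            class = "backbone_coords")
}

# CA trace only -- cheap path for lRMSD analytics on large ensembles
.ca_trace <- function(angles, geometry = ideal_geometry()) {
  if (is.vector(angles)) angles <- matrix(angles, ncol = 3L, byrow = TRUE)
  n <- nrow(angles)
  g <- geometry
  N  <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * .DEG
  Cc <- CA + g$b_ca_c * c(-cos(th), sin(th), 0)
  out <- matrix(NA_real_, n, 3L)
  out[1L, ] <- CA
  if (n > 1L) {
    for (i in 2L:n) {
      Nn <- .place_atom(N, CA, Cc, g$b_c_n, g$a_ca_c_n, angles[i - 1L, 2L])
      CAn <- .place_atom(CA, Cc, Nn, g$b_n_ca, g$a_c_n_ca, angles[i, 3L])
      Ccn <- .place_atom(Cc, Nn, CAn, g$b_ca_c, g$a_n_ca_c, angles[i, 1L])
      out[i, ] <- CAn
      N <- Nn; CA <- CAn; Cc <- Ccn
    }
  }
  out
}

#' Measure backbone dihedrals from coordinates
#'
#' Inverse of \code{\link{build_coordinates}}: phi(i) =
#' C(i-1)-N(i)-CA(i)-C(i), psi(i) = N(i)-CA(i)-C(i)-N(i+1), omega(i) =
#' CA(i-1)-C(i-1)-N(i)-CA(i). The kinematically inert terminal angles
#' (phi and omega of residue 1, psi of residue n) are reported as \code{NA}.
#'
#' @param coords a \code{backbone_coords} object (complete N/CA/C required).
#' @return n x 3 matrix of (phi, psi, omega) in degrees with \code{NA}
#'   sentinels at the inert slots.
#' @export
measure_dihedrals <- function(coords) {
  if (!inherits(coords, "backbone_coords"))
    stop("coords must be a backbone_coords object")
  n <- nrow(coords$CA)
  for (atom in c("N", "CA", "C")) {
    miss <- which(apply(coords[[atom]], 1L, function(r) any(!is.finite(r))))
    if (length(miss))
      stop("missing backbone atom ", atom, " at residue ", miss[1L])
  }
  ang <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("phi", "psi", "omega")))
  N <- coords$N; CA <- coords$CA; Cc <- coords$C
  for (i in seq_len(n)) {
    if (i > 1L) {
      ang[i, 1L] <- dihedral_angle(Cc[i - 1L, ], N[i, ], CA[i, ], Cc[i, ])
      ang[i, 3L] <- dihedral_angle(CA[i - 1L, ], Cc[i - 1L, ], N[i, ], CA[i, ])
    }
    if (i < n)
      ang[i, 2L] <- dihedral_angle(N[i, ], CA[i, ], Cc[i, ], N[i + 1L, ])
  }
  ang
}

#' @export
print.backbone_coords <- function(x, ...) {
  n <- nrow(x$CA)
  ngly <- sum(x$sequence == "G")
  cat("Backbone coordinates: ", n, " residues, ",
      5L * n - ngly, " atoms (N, CA, C, O",
      if (ngly < n) ", CB" else "", ")\n", sep = "")
  invisible(x)
}
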