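# Least RMSD over CA atoms after optimal rigid-body superposition (Kabsch).

# Kabsch on two m x 3 matrices; returns the proper rotation that best maps
# centered A onto centered B.
.kabsch_rotation <- function(A, B) {
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Least RMSD between CA coordinate sets
#'
#' Optimal-superposition (Kabsch) root-mean-square deviation over
#' corresponding CA atoms. Proper rotations only (no reflections), so the
#' measure distinguishes mirror images.
#'
#' @param a,b m x 3 coordinate matrices with corresponding rows.
#' @return lRMSD in Angstrom.
#' @export
lrmsd_coords <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("inputs must be m x 3 coordinate matrices")
  if (nrow(a) != nrow(b))
    stop("length mismatch: ", nrow(a), " vs ", nrow(b), " atoms")
  if (identical(unname(a), unname(b))) return(0)
  m <- nrow(a)
  ac <- a - rep(colMeans(a), each = m)
  bc <- b - rep(colMeans(b), each = m)
  R <- .kabsch_rotation(ac, bc)
  dif <- ac %*% R - bc
  sqrt(sum(dif * dif) / m)
}

#' Least RMSD between two conformations
#'
#' @param a,b \code{conformation}s of equal length (or m x 3 CA matrices).
#' @return lRMSD over CA atoms, in Angstrom.
#' @examples
#' x <- extended_conformation("AAAAAA")
#' lrmsd(x, x)
#' @export
lrmsd <- function(a, b) {
  A <- if (inherits(a, "conformation")) ca_coordinates(a) else a
  B <- if (inherits(b, "conformation")) ca_coordinates(b) else b
  lrmsd_coords(A, B)
}
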