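# Synthetic toy systems: planted targets, enumerable libraries, and a
# separable toy energy with a known global optimum. These make every stage of
# the search testable offline, independently of the physical potential.

#' Separable toy energy with a known optimum
#'
#' E = weight * sum over 3-mer windows of the squared angular deviation
#' (wrapped to +/-180) of the window's 9 angles from a per-window reference.
#' Because every window's reference agrees with a single global reference
#' conformation, the global minimum is 0 and is attained exactly at the
#' reference. The surface is separable by construction, so brute-force optima
#' over small libraries are enumerable; it stands in for the rugged physical
#' surface when testing the search machinery.
#'
#' @param reference a \code{conformation} or n x 3 angle matrix giving the
#'   per-window reference angles.
#' @param weight positive scale factor.
#' @param counter shared \code{\link{budget_counter}}.
#' @return An \code{energy_model}.
#' @export
toy_energy_model <- function(reference, weight = 1,
                             counter = budget_counter()) {
  ref <- if (inherits(reference, "conformation")) reference$angles else
    reference
  if (is.vector(ref)) ref <- .vec_to_angles(ref)
  n <- nrow(ref)
  if (n < 3L) stop("toy energy requires n >= 3")
  refv <- .angles_to_vec(wrap_angle(ref))
  # multiplicity: number of 3-mer windows containing each residue's slots
  res <- rep(seq_len(n), each = 3L)
  mult <- pmin(n - 2L, res) - pmax(1L, res - 2L) + 1L
  wmult <- weight * mult
  score <- function(angles, sequence) {
    v <- if (is.matrix(angles)) .angles_to_vec(angles) else angles
    d <- abs(v - refv) %% 360
    d <- pmin(d, 360 - d)
    sum(wmult * d * d)
  }
  energy_model("toy", score, counter = counter)
}

#' Construct a synthetic toy system with a planted target
#'
#' Draws a random sequence and a planted target conformation from
#' secondary-structure basins, then builds a synthetic fragment library whose
#' first entry in every window is the planted window configuration (the
#' reachability certificate), padded with decoy entries. Selecting the
#' certified entry in every window reconstructs the target exactly.
#'
#' @param n chain length (>= 3).
#' @param entries_per_window library entries per window including the planted
#'   one (>= 1).
#' @param weights basin mixture weights for decoy entries.
#' @param sigma decoy phi/psi noise, degrees.
#' @param seed integer seed; the whole system is deterministic given it.
#' @param plant insert the target's window configurations into the library
#'   (default \code{TRUE}). With \code{plant = FALSE} the target is not
#'   exactly constructible, and conflicts between overlapping windows create
#'   a frustrated, multi-minimum landscape.
#' @return An object of class \code{toy_system}: list with \code{sequence},
#'   \code{library}, \code{target} (a \code{conformation}),
#'   \code{certificate} (per-window planted entry index, \code{NULL} when
#'   unplanted), and \code{seed}.
#' @export
make_toy_system <- function(n, entries_per_window = 3L,
                            weights = c(helix = 1, strand = 1, loop = 0.5),
                            sigma = 10, seed = 1L, plant = TRUE) {
  n <- as.integer(n)
  if (n < 3L) stop("toy systems require n >= 3")
  if (entries_per_window < 1L) stop("entries_per_window must be >= 1")
  sys <- .with_seed(seed, {
    sequence <- sample(.AA1, n, replace = TRUE)
    basins <- sample(c("helix", "strand"), n, replace = TRUE)
    ang <- t(vapply(basins, function(b) {
      c(wrap_angle(.BASINS[[b]] + stats::rnorm(2, 0, sigma)),
        wrap_angle(180 + stats::rnorm(1, 0, 2)))
    }, numeric(3L)))
    dimnames(ang) <- NULL
    list(sequence = sequence, angles = ang)
  })
  target <- conformation(sys$sequence, sys$angles)
  lib <- synthetic_fragment_library(
    n, entries_per_window = entries_per_window, weights = weights,
    sigma = sigma, planted = if (plant) target else NULL,
    seed = .derive_seed(seed, 7L))
  structure(list(sequence = sys$sequence, library = lib, target = target,
                 certificate = if (plant) rep(1L, n - 2L) else NULL,
                 seed = as.integer(seed)),
            class = "toy_system")
}

#' Bundled toy study systems
#'
#' The two standard synthetic systems used throughout the package's tests
#' and examples:
#' \describe{
#'   \item{recovery}{n = 20, 3 entries per window with the target planted --
#'     a funneled landscape on which the memetic search should recover the
#'     planted native.}
#'   \item{diversity}{n = 30, 25 entries per window, target not planted --
#'     a frustrated landscape whose reachable space vastly exceeds any desk
#'     budget, emulating the regime in which the basic EA collapses
#'     population diversity while the memetic EA retains it.}
#' }
#'
#' @param name which bundled system.
#' @param seed system seed.
#' @return A \code{toy_system}.
#' @export
bundled_toy_system <- function(name = c("recovery", "diversity"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         recovery = make_toy_system(20L, entries_per_window = 3L, seed = seed),
         diversity = make_toy_system(30L, entries_per_window = 25L,
                                     seed = seed, plant = FALSE))
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Toy system: n = ", length(x$sequence), ", ",
      nrow(x$library$windows[[1L]]), " entries/window, seed ", x$seed,
      if (is.null(x$certificate)) " (unplanted, frustrated)" else
        " (planted target reachable via certificate)", "\n", sep = "")
  invisible(x)
}

#' Rebuild the planted target from a toy system's certificate
#'
#' Applies the certified library entry at every window, sweeping the chain
#' from an extended start; the result must equal the planted target.
#'
#' @param sys a \code{toy_system}.
#' @return A \code{conformation}.
#' @export
replay_certificate <- function(sys) {
  stopifnot(inherits(sys, "toy_system"))
  conf <- extended_conformation(sys$sequence)
  v <- .angles_to_vec(conf$angles)
  for (w in seq_along(sys$certificate))
    v <- .replace_window_vec(v, sys$library, w, sys$certificate[w])
  set_angles(conf, .vec_to_angles(v))
}
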