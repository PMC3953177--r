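# 3-mer fragment-configuration libraries and the molecular fragment
# replacement move operator. A fragment [i, i+2] covers 3 consecutive
# residues; its configuration is the 9 (phi, psi, omega) angles, stored
# residue-major (phi1 psi1 omega1 phi2 ... omega3).

.angles_to_vec <- function(angles) as.vector(t(angles))
.vec_to_angles <- function(v) {
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  colnames(m) <- c("phi", "psi", "omega")
  m
}
.window_slots <- function(w) (3L * (w - 1L) + 1L):(3L * (w - 1L) + 9L)

#' Fragment-configuration library
#'
#' Maps every window start i in 1..(n-2) to a non-empty set of 9-angle
#' configurations. Entries are stored as rows of a k x 9 matrix per window,
#' residue-major, degrees in (-180, 180].
#'
#' @param n target chain length (>= 3).
#' @param windows list of n-2 numeric matrices with 9 columns (one may pass a
#'   single matrix to share one pool across all windows).
#' @param source free-text provenance tag.
#' @param seed creation seed recorded as metadata.
#' @param policy window-assignment policy tag ("pooled" or "positional").
#' @return An object of class \code{fragment_library}.
#' @export
fragment_library <- function(n, windows, source = "user", seed = NA_integer_,
                             policy = "pooled") {
  n <- as.integer(n)
  if (n < 3L) stop("fragment windows require n >= 3")
  if (is.matrix(windows)) windows <- rep(list(windows), n - 2L)
  if (length(windows) != n - 2L)
    stop("windows must cover exactly 1..", n - 2L)
  windows <- lapply(seq_along(windows), function(w) {
    m <- windows[[w]]
    if (is.vector(m)) m <- matrix(m, nrow = 1L)
    if (!is.matrix(m) || ncol(m) != 9L || nrow(m) < 1L)
      stop("window ", w, " must be a non-empty matrix with 9 angle columns")
    m[] <- wrap_angle(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  structure(list(n = n, windows = windows,
                 meta = list(source = source, seed = seed, policy = policy)),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  k <- vapply(x$windows, nrow, integer(1))
  cat("Fragment library: n = ", x$n, ", ", length(x$windows),
      " windows, ", if (min(k) == max(k)) paste0(min(k), " entries/window")
      else paste0(min(k), "-", max(k), " entries/window"),
      " (", x$meta$source, ", policy ", x$meta$policy, ")\n", sep = "")
  invisible(x)
}

# fast path: replace window w of a residue-major angle vector with library
# entry 'entry'; no validation
.replace_window_vec <- function(v, lib, w, entry) {
  v[.window_slots(w)] <- lib$windows[[w]][entry, ]
  v
}

#' Molecular fragment replacement
#'
#' Draws a window start uniformly over 1..(n-2) and a configuration uniformly
#' over that window's entries, and returns a new conformation differing from
#' the input only in the 9 angles of the window. The input is untouched and
#' the child's caches are cleared.
#'
#' @param conf a \code{conformation}.
#' @param lib a \code{fragment_library} covering the chain.
#' @param window,entry optional forced window start / entry index (used by
#'   the deterministic sweep and in tests); when \code{NULL} they are drawn
#'   uniformly from the current RNG stream.
#' @return the child \code{conformation}.
#' @export
replace_fragment <- function(conf, lib, window = NULL, entry = NULL) {
  stopifnot(inherits(conf, "conformation"), inherits(lib, "fragment_library"))
  n <- length(conf$sequence)
  if (n < 3L) stop("fragment replacement requires n >= 3")
  if (lib$n != n) stop("library built for n = ", lib$n, ", chain has n = ", n)
  if (is.null(window)) window <- sample.int(n - 2L, 1L)
  k <- nrow(lib$windows[[window]])
  if (k < 1L) stop("empty configuration list for window ", window)
  if (is.null(entry)) entry <- sample.int(k, 1L)
  v <- .replace_window_vec(.angles_to_vec(conf$angles), lib, window, entry)
  conf$angles <- .vec_to_angles(v)
  conf$coords <- NULL
  conf$energy <- NULL
  conf
}

#' Randomize a conformation by a chain sweep of fragment replacements
#'
#' Performs exactly n - 2 fragment configuration replacements, one per window
#' position swept along the chain, to turn a starting (typically extended)
#' conformation into a random but realistic one. With single-entry windows
#' the outcome is fully determined.
#'
#' @inheritParams replace_fragment
#' @return the randomized \code{conformation}.
#' @export
randomize_conformation <- function(conf, lib) {
  stopifnot(inherits(conf, "conformation"), inherits(lib, "fragment_library"))
  n <- length(conf$sequence)
  if (lib$n != n) stop("library built for n = ", lib$n, ", chain has n = ", n)
  v <- .angles_to_vec(conf$angles)
  for (w in seq_len(n - 2L)) {
    k <- nrow(lib$windows[[w]])
    e <- if (k == 1L) 1L else sample.int(k, 1L)
    v <- .replace_window_vec(v, lib, w, e)
  }
  conf$angles <- .vec_to_angles(v)
  conf$coords <- NULL
  conf$energy <- NULL
  conf
}

# vector-level randomizing sweep used in the search hot loop
.randomize_vec <- function(v, lib) {
  for (w in seq_along(lib$windows)) {
    k <- nrow(lib$windows[[w]])
    e <- if (k == 1L) 1L else sample.int(k, 1L)
    v[.window_slots(w)] <- lib$windows[[w]][e, ]
  }
  v
}

#' Build a fragment library from known structures
#'
#' Measures the backbone dihedrals of each source structure, slides a
#' 3-residue window along it, and pools the resulting 9-angle configurations.
#' Under the default position-independent policy every target window receives
#' the full pool; under the positional policy window i receives only the
#' configurations measured at window i of each source (sources must then be
#' at least as long as the target). Inert terminal slots of a source
#' (phi/omega of its first residue, psi of its last) are filled with 180.
#' Duplicates are retained, so uniform sampling weights by observed
#' frequency.
#'
#' @param sources a list of \code{backbone_coords} objects,
#'   \code{conformation}s, or paths to PDB files (read as backbone).
#' @param n target chain length.
#' @param policy "pooled" (default) or "positional".
#' @return A \code{fragment_library}.
#' @export
build_library_from_structures <- function(sources, n,
                                          policy = c("pooled", "positional")) {
  policy <- match.arg(policy)
  n <- as.integer(n)
  if (n < 3L) stop("target must have n >= 3")
  per_source <- lapply(sources, function(s) {
    if (is.character(s)) s <- read_pdb_backbone(s)$coords
    if (inherits(s, "conformation")) s <- coordinates(s)
    if (!inherits(s, "backbone_coords"))
      stop("sources must be PDB paths, conformations or backbone_coords")
    L <- nrow(s$CA)
    if (L < 3L) stop("source structure too short for 3-mers (", L, " residues)")
    ang <- measure_dihedrals(s)
    ang[is.na(ang)] <- 180
    v <- .angles_to_vec(ang)
    t(vapply(seq_len(L - 2L), function(w) v[.window_slots(w)], numeric(9L)))
  })
  if (policy == "pooled") {
    pool <- do.call(rbind, per_source)
    lib <- fragment_library(n, pool, source = "structures", policy = policy)
  } else {
    short <- which(vapply(per_source, nrow, integer(1)) < n - 2L)
    if (length(short))
      stop("positional policy requires sources with >= n - 2 windows")
    windows <- lapply(seq_len(n - 2L), function(w)
      do.call(rbind, lapply(per_source, function(m) m[w, , drop = FALSE])))
    lib <- fragment_library(n, windows, source = "structures", policy = policy)
  }
  lib
}

.BASINS <- list(helix = c(phi = -57, psi = -47),
                strand = c(phi = -129, psi = 124))

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  expr
}

#' Generate a synthetic fragment library
#'
#' Samples per-window configurations from a mixture of secondary-structure
#' angle basins (helix phi = -57, psi = -47; strand phi = -129, psi = 124;
#' loop uniform) with Gaussian noise on phi/psi and near-trans omega. If a
#' planted target is supplied, its 9-angle window configurations are inserted
#' verbatim as the first entry of every window, so the target conformation is
#' exactly constructible from the library.
#'
#' @param n chain length.
#' @param entries_per_window configurations per window (>= 1), counting the
#'   planted entry when planting is requested.
#' @param weights named mixture weights over \code{helix}, \code{strand},
#'   \code{loop}; must have positive total mass.
#' @param sigma Gaussian noise on basin phi/psi, degrees.
#' @param omega_sigma Gaussian noise on trans omega, degrees.
#' @param planted optional planted target: a \code{conformation} or n x 3
#'   angle matrix.
#' @param seed optional local seed (ambient RNG state is preserved).
#' @return A \code{fragment_library}.
#' @export
synthetic_fragment_library <- function(n, entries_per_window = 5L,
                                       weights = c(helix = 1, strand = 1,
                                                   loop = 1),
                                       sigma = 10, omega_sigma = 2,
                                       planted = NULL, seed = NULL) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be >= 3")
  if (entries_per_window < 1L) stop("entries_per_window must be >= 1")
  w <- c(helix = 0, strand = 0, loop = 0)
  w[names(weights)] <- weights
  if (sum(w) <= 0) stop("mixture weights must have positive total mass")
  planted_vec <- NULL
  if (!is.null(planted)) {
    pa <- if (inherits(planted, "conformation")) planted$angles else
      .check_angles(planted, n)
    planted_vec <- .angles_to_vec(wrap_angle(pa))
  }
  .with_seed(seed, {
    draw_entry <- function() {
      basin <- sample(names(w), 1L, prob = w)
      ent <- numeric(9L)
      for (r in 0:2) {
        if (basin == "loop") {
          phi <- stats::runif(1, -180, 180)
          psi <- stats::runif(1, -180, 180)
        } else {
          phi <- .BASINS[[basin]]["phi"] + stats::rnorm(1, 0, sigma)
          psi <- .BASINS[[basin]]["psi"] + stats::rnorm(1, 0, sigma)
        }
        om <- 180 + stats::rnorm(1, 0, omega_sigma)
        ent[3 * r + 1:3] <- wrap_angle(c(phi, psi, om))
      }
      ent
    }
    windows <- lapply(seq_len(n - 2L), function(wi) {
      k <- entries_per_window
      rows <- list()
      if (!is.null(planted_vec)) {
        rows[[1L]] <- planted_vec[.window_slots(wi)]
        k <- k - 1L
      }
      for (i in seq_len(k)) rows[[length(rows) + 1L]] <- draw_entry()
      do.call(rbind, rows)
    })
    fragment_library(n, windows, source = "synthetic",
                     seed = if (is.null(seed)) NA_integer_ else seed)
  })
}

#' Write a fragment library as TSV
#'
#' Native tab-separated dialect: a header comment
#' \code{# fraglib v1 n=<n> policy=<policy>} followed by one row per
#' configuration: window_start, the 9 angles (6 decimals), and a source tag.
#'
#' @param lib a \code{fragment_library}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fraglib <- function(lib, path) {
  stopifnot(inherits(lib, "fragment_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fraglib v1 n=%d policy=%s", lib$n, lib$meta$policy),
             con)
  for (w in seq_along(lib$windows)) {
    m <- lib$windows[[w]]
    for (r in seq_len(nrow(m))) {
      writeLines(paste(c(w, sprintf("%.6f", m[r, ]), lib$meta$source),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a fragment library from TSV
#'
#' @param path file written by \code{\link{write_fraglib}}.
#' @return A \code{fragment_library}.
#' @export
read_fraglib <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# fraglib v1 ", lines[1L]))
    stop("not a fraglib v1 file: ", path)
  hdr <- lines[1L]
  n <- as.integer(sub(".* n=([0-9]+).*", "\\1", hdr))
  policy <- sub(".* policy=(\\S+).*", "\\1", hdr)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("fraglib file has no configurations")
  parts <- strsplit(body, "\t", fixed = TRUE)
  ws <- as.integer(vapply(parts, `[[`, "", 1L))
  ang <- t(vapply(parts, function(p) as.numeric(p[2:10]), numeric(9L)))
  src <- vapply(parts, function(p) if (length(p) >= 11L) p[[11L]] else "",
                character(1))
  windows <- lapply(seq_len(n - 2L), function(w) {
    rows <- which(ws == w)
    if (!length(rows)) stop("window ", w, " missing from ", path)
    ang[rows, , drop = FALSE]
  })
  fragment_library(n, windows, source = src[1L], policy = policy)
}
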