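# Containers: the evolving fixed-size population P and the running decoy
# ensemble Omega (union of the populations of every generation, initial
# population included).

#' Population of scored conformations
#'
#' A fixed-size set of conformations with scored energies, stored compactly
#' as residue-major angle rows.
#'
#' @param sequence residue codes shared by all members.
#' @param angles m x 3n matrix, one residue-major angle row per member.
#' @param energy numeric vector of scored energies, length m.
#' @param member_id stable lineage identifiers.
#' @param generation generation index of this population.
#' @return An object of class \code{population}.
#' @export
population <- function(sequence, angles, energy, member_id = seq_len(nrow(angles)),
                       generation = 0L) {
  if (nrow(angles) != length(energy))
    stop("every population member must carry a scored energy")
  if (anyNA(energy)) stop("unscored member in population")
  structure(list(sequence = sequence, angles = angles, energy = energy,
                 member_id = as.integer(member_id),
                 generation = as.integer(generation)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Population: ", nrow(x$angles), " conformations, generation ",
      x$generation, ", energies [", signif(min(x$energy), 6), ", ",
      signif(max(x$energy), 6), "]\n", sep = "")
  invisible(x)
}

#' Extract one member as a conformation
#'
#' @param pop a \code{population}.
#' @param i member index.
#' @return A \code{conformation} with its cached energy set.
#' @export
population_member <- function(pop, i) {
  conf <- conformation(pop$sequence, .vec_to_angles(pop$angles[i, ]),
                       generation = pop$generation)
  conf$energy <- pop$energy[i]
  conf
}

#' Decoy ensemble (Omega)
#'
#' The running union of per-generation populations of a run: one row per
#' retained decoy with its angles, lineage, generation and energy. For a
#' single run the size is pop_size * (completed generations + 1), the
#' initial population included.
#'
#' @param sequence residue codes.
#' @param angles |Omega| x 3n residue-major angle matrix.
#' @param meta data frame with columns \code{decoy}, \code{generation},
#'   \code{member_id}, \code{parent_id}, \code{energy}.
#' @param geometry idealized geometry for coordinate realization.
#' @return An object of class \code{decoy_ensemble}.
#' @export
decoy_ensemble <- function(sequence, angles, meta,
                           geometry = ideal_geometry()) {
  need <- c("decoy", "generation", "member_id", "parent_id", "energy")
  if (!all(need %in% names(meta)))
    stop("meta must have columns: ", paste(need, collapse = ", "))
  if (nrow(angles) != nrow(meta)) stop("angles/meta row mismatch")
  structure(list(sequence = sequence, angles = angles, meta = meta,
                 geometry = geometry),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat("Decoy ensemble: ", nrow(x$angles), " decoys over generations 0-",
      max(x$meta$generation), " (n = ", length(x$sequence), ")\n", sep = "")
  invisible(x)
}

#' @export
length.decoy_ensemble <- function(x) nrow(x$angles)

#' Extract one decoy as a conformation
#'
#' @param ens a \code{decoy_ensemble}.
#' @param i decoy row index.
#' @return A \code{conformation} with cached energy.
#' @export
ensemble_member <- function(ens, i) {
  conf <- conformation(ens$sequence, .vec_to_angles(ens$angles[i, ]),
                       geometry = ens$geometry,
                       generation = ens$meta$generation[i],
                       parent = ens$meta$parent_id[i])
  conf$energy <- ens$meta$energy[i]
  conf
}

#' Pool several decoy ensembles
#'
#' Concatenates runs (e.g. the 3 independent runs of the standard protocol)
#' into one ensemble; lineage ids are offset so they stay unique.
#'
#' @param ... \code{decoy_ensemble} objects over the same sequence.
#' @return A pooled \code{decoy_ensemble}.
#' @export
pool_ensembles <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && is.list(runs[[1L]]) &&
      !inherits(runs[[1L]], "decoy_ensemble")) runs <- runs[[1L]]
  stopifnot(length(runs) >= 1L)
  seqs <- vapply(runs, function(r) paste(r$sequence, collapse = ""), "")
  if (length(unique(seqs)) != 1L)
    stop("cannot pool ensembles over different sequences")
  off <- 0L
  metas <- list()
  for (k in seq_along(runs)) {
    m <- runs[[k]]$meta
    m$member_id <- m$member_id + off
    m$parent_id <- m$parent_id + off
    m$run <- k
    off <- off + max(m$member_id)
    metas[[k]] <- m
  }
  meta <- do.call(rbind, metas)
  meta$decoy <- seq_len(nrow(meta))
  decoy_ensemble(runs[[1L]]$sequence,
                 do.call(rbind, lapply(runs, `[[`, "angles")),
                 meta, runs[[1L]]$geometry)
}
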