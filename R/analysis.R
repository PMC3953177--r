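# Results-section analytics over decoy ensembles: lowest-lRMSD summaries,
# 95th-percentile energy reduction, energy-vs-lRMSD tables, lRMSD histograms,
# and per-population structural diversity.

# CA traces for ensemble rows, computed once per unique member id
.ensemble_ca <- function(ens, rows = seq_len(nrow(ens$angles))) {
  cache <- new.env(parent = emptyenv())
  lapply(rows, function(r) {
    key <- as.character(ens$meta$member_id[r])
    got <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(got)) {
      got <- .ca_trace(.vec_to_angles(ens$angles[r, ]), ens$geometry)
      assign(key, got, envir = cache)
    }
    got
  })
}

#' Per-decoy lRMSD to a native structure
#'
#' @param ens a \code{decoy_ensemble}.
#' @param native the native \code{conformation} (or an n x 3 CA matrix).
#' @return numeric vector of lRMSDs, one per decoy.
#' @export
ensemble_lrmsd <- function(ens, native) {
  nat <- if (inherits(native, "conformation")) ca_coordinates(native) else
    native
  if (nrow(nat) != length(ens$sequence))
    stop("native length does not match ensemble sequence")
  cas <- .ensemble_ca(ens)
  vapply(cas, function(ca) lrmsd_coords(ca, nat), numeric(1))
}

#' Lowest lRMSD over an ensemble
#'
#' @inheritParams ensemble_lrmsd
#' @return the minimum lRMSD to the native over all decoys.
#' @export
lowest_lrmsd <- function(ens, native) min(ensemble_lrmsd(ens, native))

#' Lowest-lRMSD summary over independent runs
#'
#' The standard reporting statistic: for each run, the lowest lRMSD to the
#' known native structure over the run's ensemble Omega; the average and
#' minimum of those per-run minima are returned (reported as Avg(Min) in
#' benchmark tables).
#'
#' @param runs list of \code{decoy_ensemble}s (or \code{decoy_run}s).
#' @param native the native \code{conformation}.
#' @return named numeric: \code{average} and \code{minimum}; per-run minima
#'   as attribute \code{per_run}.
#' @export
lowest_lrmsd_summary <- function(runs, native) {
  if (!length(runs)) stop("at least one run required")
  mins <- vapply(runs, function(r) {
    if (inherits(r, "decoy_run")) r <- r$ensemble
    lowest_lrmsd(r, native)
  }, numeric(1))
  structure(c(average = mean(mins), minimum = min(mins)), per_run = mins)
}

#' Reduce an ensemble to its lowest-energy 5 percent
#'
#' Retains exactly ceiling(0.05 |Omega|) decoys, the lowest-energy ones
#' ("95th percentile according to energies" read as the best 5 percent --
#' lower energy is higher fitness throughout). Ties at the threshold are
#' broken by decoy order. The opposite reading is available via
#' \code{keep = "worst"} for completeness.
#'
#' @param ens a \code{decoy_ensemble}.
#' @param fraction fraction retained (default 0.05).
#' @param keep "best" (default, lowest energies) or "worst".
#' @return A \code{decoy_ensemble} tagged with the selection rule.
#' @export
reduce_p95 <- function(ens, fraction = 0.05, keep = c("best", "worst")) {
  keep <- match.arg(keep)
  m <- nrow(ens$angles)
  if (!m) stop("empty ensemble")
  sz <- ceiling(fraction * m)
  e <- if (keep == "best") ens$meta$energy else -ens$meta$energy
  rows <- order(e, method = "radix")[seq_len(sz)]
  rows <- sort(rows)
  out <- decoy_ensemble(ens$sequence, ens$angles[rows, , drop = FALSE],
                        ens$meta[rows, , drop = FALSE], ens$geometry)
  out$selection <- sprintf("p95-%s (%d of %d)", keep, sz, m)
  out
}

#' Median pairwise lRMSD of a population
#'
#' The structural-diversity measure: the median of the lRMSDs between every
#' pair of conformations in a population. When the pair count exceeds
#' \code{max_pairs}, pairs are subsampled uniformly and the result is flagged
#' with attribute \code{subsampled = TRUE}.
#'
#' @param pop a \code{population} (or a \code{decoy_ensemble} treated as one
#'   set).
#' @param max_pairs exhaustive-enumeration cap (default 50000).
#' @param geometry idealized geometry for coordinate realization.
#' @return the median pairwise lRMSD in Angstrom.
#' @export
median_pairwise_lrmsd <- function(pop, max_pairs = 50000L,
                                  geometry = ideal_geometry()) {
  ang <- if (inherits(pop, "population")) pop$angles else pop$angles
  m <- nrow(ang)
  if (m < 2L) stop("pairwise diversity needs at least 2 members")
  cas <- lapply(seq_len(m), function(r)
    .ca_trace(.vec_to_angles(ang[r, ]), geometry))
  npairs <- m * (m - 1) / 2
  if (npairs <= max_pairs) {
    pr <- t(utils::combn(m, 2L))
    sub <- FALSE
  } else {
    pr <- cbind(sample.int(m, max_pairs, TRUE), sample.int(m, max_pairs, TRUE))
    pr <- pr[pr[, 1L] != pr[, 2L], , drop = FALSE]
    sub <- TRUE
  }
  val <- stats::median(vapply(seq_len(nrow(pr)), function(q)
    lrmsd_coords(cas[[pr[q, 1L]]], cas[[pr[q, 2L]]]), numeric(1)))
  attr(val, "subsampled") <- sub
  val
}

#' Energy versus lRMSD table
#'
#' One row per decoy with its total energy and lRMSD to the native,
#' sorted by lRMSD -- the data behind energy-landscape funnel plots.
#' Decoys with lRMSD at or below 5 Angstrom are flagged as having captured
#' the native basin.
#'
#' @inheritParams ensemble_lrmsd
#' @param captured_at capture threshold in Angstrom (default 5).
#' @return data frame with columns decoy, generation, energy, lrmsd,
#'   captured.
#' @export
energy_vs_lrmsd_table <- function(ens, native, captured_at = 5) {
  lr <- ensemble_lrmsd(ens, native)
  out <- data.frame(decoy = ens$meta$decoy, generation = ens$meta$generation,
                    energy = ens$meta$energy, lrmsd = lr,
                    captured = lr <= captured_at)
  out[order(out$lrmsd, method = "radix"), , drop = FALSE]
}

#' lRMSD histogram of an ensemble
#'
#' Half-open bins [k w, (k+1) w); counts always sum to the ensemble size.
#'
#' @inheritParams ensemble_lrmsd
#' @param bin_width positive bin width in Angstrom.
#' @return data frame with columns lower, upper, count.
#' @export
lrmsd_histogram <- function(ens, native, bin_width = 1) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  lr <- ensemble_lrmsd(ens, native)
  k <- floor(lr / bin_width)
  tab <- table(k)
  kk <- 0:max(k)
  counts <- integer(length(kk))
  counts[match(as.integer(names(tab)), kk)] <- as.integer(tab)
  data.frame(lower = kk * bin_width, upper = (kk + 1) * bin_width,
             count = counts)
}
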