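# Coarse-grained potential energy: five non-local terms summed to a scalar
# fitness behind a pluggable energy-model contract, with global evaluation
# accounting. Local interactions are not modeled -- bond lengths and angles
# are fixed at ideal values, so only non-local terms vary.

#' Global evaluation-budget counter
#'
#' Reference-semantics counter shared by every scoring call of an energy
#' model. The evaluation budget, not a generation count, is the stopping
#' criterion of the search algorithms.
#'
#' @param eval_max maximum number of energy evaluations (may be \code{Inf}).
#' @return An environment of class \code{budget_counter} with fields
#'   \code{count} and \code{max}.
#' @export
budget_counter <- function(eval_max = Inf) {
  e <- new.env(parent = emptyenv())
  e$count <- 0L
  e$max <- eval_max
  class(e) <- "budget_counter"
  e
}

#' @export
print.budget_counter <- function(x, ...) {
  cat("Budget counter: ", x$count, " / ",
      if (is.finite(x$max)) x$max else "unlimited", " evaluations\n", sep = "")
  invisible(x)
}

#' @rdname budget_counter
#' @param counter a \code{budget_counter}.
#' @export
budget_spent <- function(counter) counter$count

#' @rdname budget_counter
#' @export
budget_exhausted <- function(counter) counter$count >= counter$max

#' @rdname budget_counter
#' @export
reset_budget <- function(counter, eval_max = counter$max) {
  counter$count <- 0L
  counter$max <- eval_max
  invisible(counter)
}

#' Energy-model contract
#'
#' An energy model scores a conformation from its angles (realizing
#' coordinates if its functional form needs them). Scores are deterministic
#' given coordinates and invariant under rigid transforms. Every call of
#' \code{\link{score_energy}} increments the model's shared budget counter by
#' exactly one; \code{\link{energy_breakdown}} never increments it.
#'
#' @param name model identifier.
#' @param score_angles function(angles, sequence) -> numeric scalar.
#' @param breakdown_angles optional function(angles, sequence) -> named
#'   numeric vector of term values including \code{total}.
#' @param counter a shared \code{\link{budget_counter}}.
#' @return An object of class \code{energy_model}.
#' @export
energy_model <- function(name, score_angles, breakdown_angles = NULL,
                         counter = budget_counter()) {
  stopifnot(is.function(score_angles))
  structure(list(name = name, score_angles = score_angles,
                 breakdown_angles = breakdown_angles, counter = counter),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Energy model '", x$name, "' (", x$counter$count,
      " evaluations used)\n", sep = "")
  invisible(x)
}

#' Score a conformation (counted)
#'
#' @param model an \code{energy_model}.
#' @param conf a \code{conformation} (or an angle matrix if \code{sequence}
#'   is given).
#' @param sequence residue codes when \code{conf} is a bare angle matrix.
#' @return total energy (dimensionless score; lower is fitter).
#' @export
score_energy <- function(model, conf, sequence = NULL) {
  if (inherits(conf, "conformation")) {
    angles <- conf$angles
    sequence <- conf$sequence
  } else angles <- conf
  v <- model$score_angles(angles, sequence)
  model$counter$count <- model$counter$count + 1L
  v
}

#' Per-term energy breakdown (not counted against the budget)
#'
#' @inheritParams score_energy
#' @return named numeric vector of term values; the \code{total} entry equals
#'   the sum of the terms.
#' @export
energy_breakdown <- function(model, conf, sequence = NULL) {
  if (inherits(conf, "conformation")) {
    angles <- conf$angles
    sequence <- conf$sequence
  } else angles <- conf
  if (is.null(model$breakdown_angles)) {
    v <- model$score_angles(angles, sequence)
    return(c(total = v))
  }
  model$breakdown_angles(angles, sequence)
}

#' Parameters of the five-term coarse-grained potential
#'
#' All tunable constants of the backbone potential in one immutable table:
#' soft-core 12-6 Lennard-Jones (per-atom-type radii and well depths, cap
#' fraction), backbone hydrogen bonds (ideal N...O distance, Gaussian width,
#' hard distance tolerance, weight, minimum sequence separation), compaction
#' (hinge on the CA radius of gyration against Rg_target = a * n^b), burial
#' (CB contact-count wells per hydrophobicity class) and water-mediated
#' contacts (switched pair term in a 6.5-9.5 Angstrom shell). Energies are
#' unitless scores; only their ordering matters for selection.
#'
#' @param ... named overrides for any default entry.
#' @return A named list of class \code{amw_params}.
#' @export
amw_params <- function(...) {
  p <- list(
    # 12-6 LJ, AMBER-style atom typing; r_min_ij = radius_i + radius_j
    lj_radius = c(N = 1.824, CA = 1.908, C = 1.908, O = 1.661, CB = 1.908),
    lj_eps    = c(N = 0.170, CA = 0.109, C = 0.086, O = 0.210, CB = 0.109),
    lj_cap_frac = 0.8,       # soft-core cap at this fraction of r_min
    sep_nonlocal = 2L,       # |i-j| >= 2 for LJ, burial, water
    # hydrogen bonds: donor N(i), acceptor O(j)
    hb_d0 = 2.98,            # ideal N...O distance (Angstrom)
    hb_sigma = 0.3,          # Gaussian width
    hb_tol = 1.0,            # hard |d - d0| cutoff
    hb_w = 2.0,              # well depth per ideal bond
    sep_hbond = 3L,          # keeps i,i+4 helical bonds visible
    # compaction: hinge on Rg above the globular target
    rg_a = 2.2, rg_b = 0.38, w_compact = 1.0,
    # burial: CB contact counts within the shell
    burial_shell = 7.0,
    burial_t_hphob = 4, burial_t_polar = 2, w_burial = 0.3,
    # water-mediated contacts
    water_inner = 6.5, water_outer = 9.5, water_taper = 0.5,
    w_water = c(HH = -0.30, HP = -0.10, PP = -0.20),
    hydrophobic = .HYDROPHOBIC
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  structure(p, class = "amw_params")
}

# side-chain interaction centre: CB, or CA for glycine
.side_centers <- function(coords) {
  sc <- coords$CB
  gly <- coords$sequence == "G"
  sc[gly, ] <- coords$CA[gly, , drop = FALSE]
  sc
}

.pair_indices <- function(n, min_sep) {
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- (idx[, 2L] - idx[, 1L]) >= min_sep
  cbind(i = idx[keep, 1L], j = idx[keep, 2L])
}

#' Soft-core 12-6 Lennard-Jones term
#'
#' Sum over non-local atom pairs (sequence separation >= 2 residues) of
#' eps_ij * ((r_min_ij / r)^12 - 2 (r_min_ij / r)^6). Below the cap distance
#' c * r_min_ij the curve continues linearly with the slope at the cap, so
#' the term is finite for any input (soft penetration of van der Waals
#' spheres).
#'
#' @param coords a \code{backbone_coords} object.
#' @param params an \code{\link{amw_params}} table.
#' @return scalar energy.
#' @export
lj_term <- function(coords, params = amw_params()) {
  n <- nrow(coords$CA)
  types <- c("N", "CA", "C", "O", "CB")
  res <- rep(seq_len(n), times = length(types))
  typ <- rep(types, each = n)
  xyz <- do.call(rbind, coords[types])
  keep <- apply(xyz, 1L, function(r) all(is.finite(r)))
  res <- res[keep]; typ <- typ[keep]; xyz <- xyz[keep, , drop = FALSE]

  m <- nrow(xyz)
  if (m < 2L) return(0)
  pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  sep <- abs(res[pr[, 2L]] - res[pr[, 1L]])
  pr <- pr[sep >= params$sep_nonlocal, , drop = FALSE]
  if (!nrow(pr)) return(0)

  d <- xyz[pr[, 1L], , drop = FALSE] - xyz[pr[, 2L], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  rmin <- params$lj_radius[typ[pr[, 1L]]] + params$lj_radius[typ[pr[, 2L]]]
  eps <- sqrt(params$lj_eps[typ[pr[, 1L]]] * params$lj_eps[typ[pr[, 2L]]])
  sum(.lj_pair(r, rmin, eps, params$lj_cap_frac))
}

# vectorized pair energy with first-order soft-core continuation
.lj_pair <- function(r, rmin, eps, cap_frac) {
  rc <- cap_frac * rmin
  e <- numeric(length(r))
  out <- r >= rc
  q <- (rmin[out] / r[out])^6
  e[out] <- eps[out] * (q * q - 2 * q)
  if (any(!out)) {
    qc <- (rmin[!out] / rc[!out])^6
    ec <- eps[!out] * (qc * qc - 2 * qc)
    # dE/dr at the cap
    sl <- eps[!out] * (-12 * qc * qc + 12 * qc) / rc[!out]
    e[!out] <- ec + sl * (r[!out] - rc[!out])
  }
  e
}

#' Backbone hydrogen-bond term
#'
#' Sum over donor N(i) / acceptor O(j) pairs with |i - j| >= 3 of
#' -w_hb * g(d_NO) * h(theta): g a unit-peak Gaussian at the ideal N...O
#' distance (zero outside a hard tolerance) and h = cos^2 of the C=O...N
#' angle, gated to angles beyond 90 degrees. Always <= 0.
#'
#' @inheritParams lj_term
#' @return scalar energy (non-positive).
#' @export
hbond_term <- function(coords, params = amw_params()) {
  n <- nrow(coords$CA)
  if (n < params$sep_hbond + 1L) return(0)
  N <- coords$N; O <- coords$O; Cc <- coords$C
  e <- 0
  for (i in seq_len(n)) {
    js <- which(abs(seq_len(n) - i) >= params$sep_hbond)
    if (!length(js)) next
    d <- O[js, , drop = FALSE] - rep(N[i, ], each = length(js))
    dist <- sqrt(rowSums(d * d))
    ok <- abs(dist - params$hb_d0) <= params$hb_tol
    if (!any(ok)) next
    for (j in js[ok]) {
      v1 <- Cc[j, ] - O[j, ]             # O -> C
      v2 <- N[i, ] - O[j, ]              # O -> N
      ct <- sum(v1 * v2) / sqrt(sum(v1 * v1) * sum(v2 * v2))
      if (ct < 0) {                      # angle beyond 90 degrees
        dd <- sqrt(sum(v2 * v2))
        g <- exp(-(dd - params$hb_d0)^2 / (2 * params$hb_sigma^2))
        e <- e - params$hb_w * g * ct * ct
      }
    }
  }
  e
}

#' Compaction term
#'
#' Hinge penalty on expansion: w_c * max(0, Rg - Rg_target)^2 with Rg the CA
#' radius of gyration and Rg_target = a * n^b (globular scaling). Collapse
#' below the target is never rewarded.
#'
#' @inheritParams lj_term
#' @return scalar energy (non-negative).
#' @export
compaction_term <- function(coords, params = amw_params()) {
  ca <- coords$CA
  n <- nrow(ca)
  cen <- colMeans(ca)
  rg <- sqrt(mean(rowSums((ca - rep(cen, each = n))^2)))
  tgt <- params$rg_a * n^params$rg_b
  params$w_compact * max(0, rg - tgt)^2
}

#' Burial term
#'
#' For each residue, counts side-chain centres (CB; CA for glycine) within
#' the burial shell at sequence separation >= 2 and applies a
#' piecewise-linear well: hydrophobic residues are penalized for low contact
#' counts (exposure), polar residues for high counts (burial). Bounded below.
#'
#' @inheritParams lj_term
#' @return scalar energy.
#' @export
burial_term <- function(coords, params = amw_params()) {
  sc <- .side_centers(coords)
  n <- nrow(sc)
  counts <- burial_contact_counts(coords, params)
  hph <- coords$sequence %in% params$hydrophobic
  u <- ifelse(hph,
              params$w_burial * pmax(0, params$burial_t_hphob - counts),
              params$w_burial * pmax(0, counts - params$burial_t_polar))
  sum(u)
}

#' @rdname burial_term
#' @return \code{burial_contact_counts}: integer vector of per-residue
#'   contact counts.
#' @export
burial_contact_counts <- function(coords, params = amw_params()) {
  sc <- .side_centers(coords)
  n <- nrow(sc)
  counts <- integer(n)
  if (n < 2L) return(counts)
  pr <- .pair_indices(n, params$sep_nonlocal)
  if (nrow(pr)) {
    d <- sc[pr[, 1L], , drop = FALSE] - sc[pr[, 2L], , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    inside <- r <= params$burial_shell
    counts <- tabulate(c(pr[inside, 1L], pr[inside, 2L]), nbins = n)
  }
  counts
}

# smooth switching function: 1 on [inner, outer], cosine ramps of width
# taper on both sides, 0 beyond
.water_switch <- function(r, inner, outer, taper) {
  s <- numeric(length(r))
  s[r >= inner & r <= outer] <- 1
  lo <- r > inner - taper & r < inner
  s[lo] <- 0.5 * (1 - cos(pi * (r[lo] - (inner - taper)) / taper))
  hi <- r > outer & r < outer + taper
  s[hi] <- 0.5 * (1 + cos(pi * (r[hi] - outer) / taper))
  s
}

#' Water-mediated contact term
#'
#' Sum over side-chain centre pairs at sequence separation >= 2 of a
#' class-pair weight times a smooth switching function equal to 1 inside the
#' water shell (6.5-9.5 Angstrom by default) and 0 beyond a short taper.
#'
#' @inheritParams lj_term
#' @return scalar energy.
#' @export
water_term <- function(coords, params = amw_params()) {
  sc <- .side_centers(coords)
  n <- nrow(sc)
  if (n < 2L) return(0)
  pr <- .pair_indices(n, params$sep_nonlocal)
  if (!nrow(pr)) return(0)
  d <- sc[pr[, 1L], , drop = FALSE] - sc[pr[, 2L], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  s <- .water_switch(r, params$water_inner, params$water_outer,
                     params$water_taper)
  hph <- coords$sequence %in% params$hydrophobic
  cls <- ifelse(hph[pr[, 1L]] & hph[pr[, 2L]], "HH",
                ifelse(!hph[pr[, 1L]] & !hph[pr[, 2L]], "PP", "HP"))
  sum(params$w_water[cls] * s)
}

#' Total coarse-grained energy and its breakdown
#'
#' \code{score_total} sums the five non-local terms; the \code{total} entry of
#' \code{amw_breakdown} equals that sum to within 1e-9 by construction.
#'
#' @param conf a \code{conformation}.
#' @param params an \code{\link{amw_params}} table.
#' @return \code{score_total}: scalar energy. \code{amw_breakdown}: named
#'   vector (e_lj, e_hbond, e_compaction, e_burial, e_water, total).
#' @export
score_total <- function(conf, params = amw_params()) {
  unname(amw_breakdown(conf, params)["total"])
}

#' @rdname score_total
#' @export
amw_breakdown <- function(conf, params = amw_params()) {
  coords <- if (inherits(conf, "backbone_coords")) conf else coordinates(conf)
  v <- c(e_lj = lj_term(coords, params),
         e_hbond = hbond_term(coords, params),
         e_compaction = compaction_term(coords, params),
         e_burial = burial_term(coords, params),
         e_water = water_term(coords, params))
  c(v, total = sum(v))
}

#' Five-term energy model
#'
#' Wraps the five-term potential as a pluggable \code{\link{energy_model}}
#' bound to a sequence, with a shared budget counter. Any other potential
#' (e.g. an external coarse-grained scoring adapter) can stand behind the
#' same contract.
#'
#' @param sequence residue codes the model will score.
#' @param params an \code{\link{amw_params}} table.
#' @param geometry idealized geometry used to realize coordinates.
#' @param counter shared \code{\link{budget_counter}}.
#' @return An \code{energy_model}.
#' @export
amw_energy_model <- function(sequence, params = amw_params(),
                             geometry = ideal_geometry(),
                             counter = budget_counter()) {
  sequence <- .check_sequence(sequence)
  score <- function(angles, seq_in) {
    co <- build_coordinates(angles, sequence, geometry)
    unname(amw_breakdown(co, params)["total"])
  }
  brk <- function(angles, seq_in) {
    co <- build_coordinates(angles, sequence, geometry)
    amw_breakdown(co, params)
  }
  energy_model("amw", score, brk, counter)
}
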