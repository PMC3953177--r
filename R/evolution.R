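# The two search algorithms: a basic evolutionary algorithm (EA) and a
# memetic EA (MEA) that additionally maps every child to a nearby local
# minimum by greedy fragment-replacement descent. Both run against a fixed
# budget of energy evaluations, never a fixed generation count.

#' Fitness-proportionate parent-selection weights
#'
#' Linear weighting of energies: w_i = (E_max - E_i) + 0.01 (E_max - E_min),
#' normalized to probabilities. The 1 percent floor keeps the worst member
#' selectable; an all-equal population degrades to the uniform law.
#'
#' @param energy numeric vector of population energies.
#' @return probability vector summing to 1.
#' @export
parent_weights <- function(energy) {
  if (!length(energy)) stop("empty population")
  emax <- max(energy)
  emin <- min(energy)
  if (emax == emin) return(rep(1 / length(energy), length(energy)))
  w <- (emax - energy) + 0.01 * (emax - emin)
  w / sum(w)
}

#' Select a parent from a scored population
#'
#' Samples a member index under the linear fitness weighting of
#' \code{\link{parent_weights}}; lower energies are proportionally more
#' likely, and a member may be selected repeatedly.
#'
#' @param pop a \code{population}.
#' @param k number of draws.
#' @return \code{select_parent_index}: integer indices;
#'   \code{select_parent}: a single parent \code{conformation}.
#' @export
select_parent_index <- function(pop, k = 1L) {
  energy <- if (inherits(pop, "population")) pop$energy else pop
  sample.int(length(energy), k, replace = TRUE, prob = parent_weights(energy))
}

#' @rdname select_parent_index
#' @export
select_parent <- function(pop) {
  stopifnot(inherits(pop, "population"))
  population_member(pop, select_parent_index(pop))
}

#' Truncation survival selection
#'
#' Merges the current population with the child set and keeps exactly the
#' pop_size lowest-energy members. Ties are broken by stable order with
#' parents preceding children (mild elitism, deterministic).
#'
#' @param parents a \code{population}.
#' @param child_angles m x 3n matrix of child angle rows (may have 0 rows).
#' @param child_energy scored child energies.
#' @param child_id child lineage ids.
#' @param pop_size survivors to keep.
#' @return A \code{population} for the next generation.
#' @export
truncation_select <- function(parents, child_angles, child_energy,
                              child_id = NULL, pop_size = nrow(parents$angles)) {
  stopifnot(inherits(parents, "population"))
  if (anyNA(child_energy)) stop("unscored child in truncation selection")
  m <- nrow(parents$angles) + length(child_energy)
  if (m < pop_size)
    stop("merged set smaller than pop_size")
  if (is.null(child_id))
    child_id <- max(parents$member_id, 0L) + seq_along(child_energy)
  all_energy <- c(parents$energy, child_energy)
  ord <- order(all_energy, method = "radix")[seq_len(pop_size)]
  np <- nrow(parents$angles)
  ang <- rbind(parents$angles, child_angles)[ord, , drop = FALSE]
  population(parents$sequence, ang, all_energy[ord],
             member_id = c(parents$member_id, child_id)[ord],
             generation = parents$generation + 1L)
}

#' Greedy minimization by fragment replacement
#'
#' Maps a conformation to a nearby local minimum: repeatedly proposes a
#' fragment replacement and accepts it only on a strict energy decrease,
#' halting when n consecutive proposals have been rejected (n the chain
#' length) or the evaluation budget is exhausted. Every proposal costs
#' exactly one energy evaluation. The returned energy never exceeds the
#' input energy.
#'
#' @param conf a \code{conformation} whose energy cache is set (it is scored
#'   once, against the budget, if not).
#' @param lib a \code{fragment_library}.
#' @param model an \code{energy_model}; its shared counter enforces the
#'   budget.
#' @param max_rejections consecutive rejections that signal a local minimum
#'   (defaults to the chain length).
#' @return the minimized \code{conformation}, with attributes
#'   \code{proposals} and \code{accepted}.
#' @export
greedy_minimize <- function(conf, lib, model,
                            max_rejections = length(conf$sequence)) {
  stopifnot(inherits(conf, "conformation"))
  v <- .angles_to_vec(conf$angles)
  e <- conf$energy
  counter <- model$counter
  if (is.null(e)) {
    if (budget_exhausted(counter)) return(conf)
    e <- score_energy(model, conf)
  }
  res <- .greedy_min_vec(v, e, lib, model, counter, max_rejections,
                         conf$sequence)
  out <- set_angles(conf, .vec_to_angles(res$v))
  out$energy <- res$e
  attr(out, "proposals") <- res$proposals
  attr(out, "accepted") <- res$accepted
  out
}

# hot path: greedy descent on a residue-major angle vector
.greedy_min_vec <- function(v, e, lib, model, counter, max_rej, sequence) {
  nw <- length(lib$windows)
  score_angles <- model$score_angles
  rej <- 0L
  props <- 0L
  acc <- 0L
  while (rej < max_rej && counter$count < counter$max) {
    w <- sample.int(nw, 1L)
    ents <- lib$windows[[w]]
    k <- nrow(ents)
    ei <- if (k == 1L) 1L else sample.int(k, 1L)
    v2 <- v
    v2[(3L * (w - 1L) + 1L):(3L * (w - 1L) + 9L)] <- ents[ei, ]
    e2 <- score_angles(v2, sequence)
    counter$count <- counter$count + 1L
    props <- props + 1L
    if (e2 < e) {
      v <- v2
      e <- e2
      acc <- acc + 1L
      rej <- 0L
    } else rej <- rej + 1L
  }
  list(v = v, e = e, proposals = props, accepted = acc)
}

#' Initial population by randomizing sweeps
#'
#' Builds pop_size conformations, each obtained from the extended
#' conformation by n - 2 fragment replacements swept along the chain, and
#' scores each once (advancing the budget counter by exactly pop_size).
#'
#' @param sequence residue codes.
#' @param lib a \code{fragment_library}.
#' @param model an \code{energy_model}.
#' @param pop_size population capacity.
#' @return A generation-0 \code{population}.
#' @export
initial_population <- function(sequence, lib, model, pop_size) {
  sequence <- .check_sequence(sequence)
  n <- length(sequence)
  if (model$counter$count + pop_size > model$counter$max)
    stop("evaluation budget cannot score the initial population")
  ext <- rep(180, 3L * n)
  ang <- matrix(NA_real_, pop_size, 3L * n)
  for (m in seq_len(pop_size)) ang[m, ] <- .randomize_vec(ext, lib)
  energy <- numeric(pop_size)
  score_angles <- model$score_angles
  counter <- model$counter
  for (m in seq_len(pop_size)) {
    energy[m] <- score_angles(ang[m, ], sequence)
    counter$count <- counter$count + 1L
  }
  population(sequence, ang, energy, member_id = seq_len(pop_size),
             generation = 0L)
}

#' Evolutionary decoy sampling
#'
#' Runs the basic EA or the memetic EA over a protein sequence. Each
#' generation, num_child children are generated by fitness-weighted parent
#' selection followed by one fragment replacement (and, in the MEA, greedy
#' minimization of every child); parents and children then compete under
#' truncation selection, the survivors forming the next fixed-size
#' population, which is appended to the running decoy ensemble Omega. The
#' loop is guarded by the evaluation budget -- checked before each child's
#' first evaluation, so an in-flight generation (or greedy descent) halts
#' when the counter reaches eval_max.
#'
#' @param sequence residue codes (vector or single string), n >= 3.
#' @param library a \code{fragment_library} covering the sequence.
#' @param energy an \code{energy_model}; its counter is reset to
#'   \code{eval_max} at the start of the run.
#' @param algorithm "mea" (memetic, default) or "ea" (basic).
#' @param pop_size population capacity (production-scale default 1000).
#' @param num_child children per generation; defaults to 250 for the MEA and
#'   4000 for the EA.
#' @param eval_max total energy-evaluation budget (production-scale default 1e7;
#'   desk-scale runs should use far less).
#' @param seed integer root seed; all randomness flows from it through
#'   named streams (init / select / move / minimize / analysis).
#' @param native optional native \code{conformation}; per-generation lowest
#'   lRMSD to it is logged.
#' @param track_diversity log the population's median pairwise lRMSD.
#' @param diversity_pairs pair subsample cap per logged generation.
#' @param diversity_every log diversity every this many generations.
#' @param geometry idealized geometry table.
#' @param verbose emit one line per generation to standard error.
#' @return An object of class \code{decoy_run}: list with \code{ensemble}
#'   (the \code{decoy_ensemble} Omega), \code{logs} (one row per completed
#'   generation plus generation 0), \code{final_population}, \code{config},
#'   \code{eval_count} and \code{generations}.
#' @examples
#' sys <- make_toy_system(8, entries_per_window = 2, seed = 1)
#' run <- sample_decoys(sys$sequence, sys$library,
#'                      toy_energy_model(sys$target),
#'                      algorithm = "mea", pop_size = 10, num_child = 4,
#'                      eval_max = 300, seed = 1)
#' run
#' @export
sample_decoys <- function(sequence, library, energy,
                          algorithm = c("mea", "ea"),
                          pop_size = 1000L, num_child = NULL,
                          eval_max = 1e7, seed,
                          native = NULL,
                          track_diversity = TRUE, diversity_pairs = 200L,
                          diversity_every = 1L,
                          geometry = ideal_geometry(), verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  sequence <- .check_sequence(sequence)
  n <- length(sequence)
  if (n < 3L) stop("searchable systems require n >= 3")
  stopifnot(inherits(library, "fragment_library"),
            inherits(energy, "energy_model"))
  if (library$n != n)
    stop("library built for n = ", library$n, ", sequence has n = ", n)
  if (missing(seed)) stop("a seed is required (no silent nondeterminism)")
  if (is.null(num_child)) num_child <- if (algorithm == "mea") 250L else 4000L
  pop_size <- as.integer(pop_size)
  num_child <- as.integer(num_child)
  if (pop_size < 2L) stop("pop_size must be >= 2")
  if (num_child < 1L) stop("num_child must be >= 1")
  if (eval_max < pop_size)
    stop("eval_max must allow scoring the initial population")
  if (!is.null(native) && length(native$sequence) != n)
    stop("native length does not match the target sequence")

  counter <- energy$counter
  reset_budget(counter, eval_max)
  streams <- rng_streams(seed, c("init", "select", "move", "minimize",
                                 "analysis"))
  score_angles <- energy$score_angles

  pop <- with_stream(streams, "init",
                     initial_population(sequence, library, energy, pop_size))

  # caches keyed by member id, for diversity / native-lRMSD logging
  ca_cache <- new.env(parent = emptyenv())
  nat_cache <- new.env(parent = emptyenv())
  native_ca <- if (!is.null(native)) ca_coordinates(native)
  member_ca <- function(id, row) {
    key <- as.character(id)
    got <- get0(key, envir = ca_cache, inherits = FALSE)
    if (is.null(got)) {
      got <- .ca_trace(.vec_to_angles(pop$angles[row, ]), geometry)
      assign(key, got, envir = ca_cache)
    }
    got
  }
  pop_diversity <- function() {
    m <- nrow(pop$angles)
    npairs <- m * (m - 1) / 2
    with_stream(streams, "analysis", {
      if (npairs <= diversity_pairs) {
        pr <- t(utils::combn(m, 2L))
      } else {
        pr <- cbind(sample.int(m, diversity_pairs, TRUE),
                    sample.int(m, diversity_pairs, TRUE))
        pr <- pr[pr[, 1L] != pr[, 2L], , drop = FALSE]
      }
      stats::median(vapply(seq_len(nrow(pr)), function(q) {
        lrmsd_coords(member_ca(pop$member_id[pr[q, 1L]], pr[q, 1L]),
                     member_ca(pop$member_id[pr[q, 2L]], pr[q, 2L]))
      }, numeric(1)))
    })
  }
  pop_native_lrmsd <- function() {
    if (is.null(native)) return(NA_real_)
    min(vapply(seq_len(nrow(pop$angles)), function(r) {
      key <- as.character(pop$member_id[r])
      got <- get0(key, envir = nat_cache, inherits = FALSE)
      if (is.null(got)) {
        got <- lrmsd_coords(member_ca(pop$member_id[r], r), native_ca)
        assign(key, got, envir = nat_cache)
      }
      got
    }, numeric(1)))
  }

  omega_angles <- list(pop$angles)
  omega_meta <- list(data.frame(generation = 0L, member_id = pop$member_id,
                                parent_id = NA_integer_,
                                energy = pop$energy))
  parent_of <- new.env(parent = emptyenv())

  log_row <- function(gen, surv, props, accs) {
    data.frame(generation = gen, eval_count = counter$count,
               energy_best = min(pop$energy),
               energy_mean = mean(pop$energy),
               energy_median = stats::median(pop$energy),
               child_survivors = surv,
               greedy_proposals = props, greedy_accepted = accs,
               diversity = if (track_diversity && gen %% diversity_every == 0L)
                 pop_diversity() else NA_real_,
               native_lrmsd = pop_native_lrmsd())
  }
  logs <- list(log_row(0L, NA_integer_, NA_integer_, NA_integer_))

  next_id <- pop_size + 1L
  gen <- 0L
  nw <- n - 2L

  while (counter$count < eval_max) {
    probs <- parent_weights(pop$energy)
    pidx <- with_stream(streams, "select",
                        sample.int(pop_size, num_child, replace = TRUE,
                                   prob = probs))
    moves <- with_stream(streams, "move", {
      list(w = sample.int(nw, num_child, replace = TRUE),
           u = stats::runif(num_child))
    })
    child_angles <- matrix(NA_real_, num_child, 3L * n)
    child_energy <- rep(NA_real_, num_child)
    child_parent <- integer(num_child)
    gprops <- 0L
    gaccs <- 0L
    scored <- 0L
    for (cix in seq_len(num_child)) {
      if (counter$count >= eval_max) break
      w <- moves$w[cix]
      ents <- library$windows[[w]]
      k <- nrow(ents)
      ei <- min(k, 1L + floor(moves$u[cix] * k))
      v <- pop$angles[pidx[cix], ]
      v[(3L * (w - 1L) + 1L):(3L * (w - 1L) + 9L)] <- ents[ei, ]
      e <- score_angles(v, sequence)
      counter$count <- counter$count + 1L
      if (algorithm == "mea") {
        res <- with_stream(streams, "minimize",
                           .greedy_min_vec(v, e, library, energy, counter,
                                           n, sequence))
        v <- res$v
        e <- res$e
        gprops <- gprops + res$proposals
        gaccs <- gaccs + res$accepted
      }
      scored <- scored + 1L
      child_angles[cix, ] <- v
      child_energy[cix] <- e
      child_parent[cix] <- pop$member_id[pidx[cix]]
    }
    if (scored == 0L) break
    keep <- seq_len(scored)
    child_ids <- next_id + keep - 1L
    next_id <- next_id + scored
    for (q in keep)
      assign(as.character(child_ids[q]), child_parent[q], envir = parent_of)
    pop <- truncation_select(pop, child_angles[keep, , drop = FALSE],
                             child_energy[keep], child_ids, pop_size)
    gen <- gen + 1L
    surv <- sum(pop$member_id %in% child_ids)
    omega_angles[[gen + 1L]] <- pop$angles
    omega_meta[[gen + 1L]] <- data.frame(
      generation = gen, member_id = pop$member_id,
      parent_id = vapply(pop$member_id, function(id) {
        p <- get0(as.character(id), envir = parent_of, inherits = FALSE)
        if (is.null(p)) NA_integer_ else as.integer(p)
      }, integer(1)),
      energy = pop$energy)
    logs[[gen + 1L]] <- log_row(gen, surv, gprops, gaccs)
    if (verbose)
      message(sprintf("gen %d: evals %d best %.4f diversity %s",
                      gen, counter$count, min(pop$energy),
                      format(logs[[gen + 1L]]$diversity, digits = 4)))
  }

  meta <- do.call(rbind, omega_meta)
  meta <- cbind(decoy = seq_len(nrow(meta)), meta)
  ens <- decoy_ensemble(sequence, do.call(rbind, omega_angles), meta,
                        geometry)
  config <- list(algorithm = algorithm, pop_size = pop_size,
                 num_child = num_child, eval_max = eval_max,
                 seed = as.integer(seed), energy = energy$name,
                 sequence = paste(sequence, collapse = ""),
                 track_diversity = track_diversity,
                 diversity_pairs = as.integer(diversity_pairs),
                 diversity_every = as.integer(diversity_every))
  structure(list(ensemble = ens, logs = do.call(rbind, logs),
                 final_population = pop, config = config,
                 config_hash = config_hash(config),
                 eval_count = counter$count, generations = gen),
            class = "decoy_run")
}

#' @export
print.decoy_run <- function(x, ...) {
  cat("Decoy sampling run (", toupper(x$config$algorithm), ", ",
      x$config$energy, " energy)\n", sep = "")
  cat("  sequence: n = ", nchar(x$config$sequence), "; pop_size ",
      x$config$pop_size, ", num_child ", x$config$num_child, "\n", sep = "")
  cat("  ", x$generations, " generations, ", x$eval_count, " / ",
      format(x$config$eval_max, scientific = FALSE),
      " energy evaluations\n", sep = "")
  cat("  ensemble Omega: ", nrow(x$ensemble$angles), " decoys; best energy ",
      signif(min(x$ensemble$meta$energy), 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.decoy_run <- function(object, native = NULL, ...) {
  logs <- object$logs
  out <- list(
    algorithm = object$config$algorithm,
    generations = object$generations,
    eval_count = object$eval_count,
    ensemble_size = nrow(object$ensemble$angles),
    best_energy = min(object$ensemble$meta$energy),
    final_diversity = utils::tail(stats::na.omit(logs$diversity), 1L),
    lowest_native_lrmsd = if (!is.null(native))
      lowest_lrmsd(object$ensemble, native) else
        utils::tail(stats::na.omit(logs$native_lrmsd), 1L))
  class(out) <- "summary.decoy_run"
  out
}

#' @export
print.summary.decoy_run <- function(x, ...) {
  cat("Run summary (", toupper(x$algorithm), "): ", x$generations,
      " generations, ", x$eval_count, " evaluations\n", sep = "")
  cat("  |Omega| = ", x$ensemble_size, ", best energy ",
      signif(x$best_energy, 6), "\n", sep = "")
  if (length(x$final_diversity))
    cat("  final population median pairwise lRMSD: ",
        signif(x$final_diversity, 4), " A\n", sep = "")
  if (length(x$lowest_native_lrmsd) && !all(is.na(x$lowest_native_lrmsd)))
    cat("  lowest lRMSD to native over Omega: ",
        signif(x$lowest_native_lrmsd, 4), " A\n", sep = "")
  invisible(x)
}

#' @export
plot.decoy_run <- function(x, which = c("energy", "diversity"), ...) {
  which <- match.arg(which)
  logs <- x$logs
  if (which == "energy") {
    graphics::plot(logs$generation, logs$energy_best, type = "l",
                   xlab = "generation", ylab = "energy",
                   main = "Best and median population energy", ...)
    graphics::lines(logs$generation, logs$energy_median, lty = 2)
    graphics::legend("topright", legend = c("best", "median"),
                     lty = c(1, 2), bty = "n")
  } else {
    ok <- !is.na(logs$diversity)
    graphics::plot(logs$generation[ok], logs$diversity[ok], type = "l",
                   xlab = "generation",
                   ylab = "median pairwise lRMSD (A)",
                   main = "Population structural diversity", ...)
  }
  invisible(x)
}
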