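# Deterministic named RNG streams. One root seed; independent streams for
# initialization, parent selection, move proposals and minimization, so that
# toggling minimization does not perturb the other streams.

.derive_seed <- function(seed, k) {
  # fixed LCG step (Park-Miller modulus), kept below 2^31
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

#' Create named deterministic RNG streams
#'
#' Each stream carries its own generator state, derived from the single root
#' seed; draws on one stream never perturb another.
#'
#' @param seed integer root seed.
#' @param names character vector of stream names.
#' @return An object of class \code{rng_streams}.
#' @export
rng_streams <- function(seed,
                        names = c("init", "select", "move", "minimize")) {
  e <- new.env(parent = emptyenv())
  old <- .save_rng_state()
  for (k in seq_along(names)) {
    set.seed(.derive_seed(seed, k))
    assign(names[k], get(".Random.seed", envir = globalenv()), envir = e)
  }
  .restore_rng_state(old)
  structure(list(states = e, seed = as.integer(seed)), class = "rng_streams")
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a named stream
#'
#' Swaps the stream's generator state in, evaluates \code{expr}, records the
#' advanced state back into the stream, and restores the ambient state.
#'
#' @param streams an \code{rng_streams} object.
#' @param name stream name.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rng_streams"))
  if (!exists(name, envir = streams$states, inherits = FALSE))
    stop("no RNG stream named '", name, "'")
  old <- .save_rng_state()
  assign(".Random.seed", get(name, envir = streams$states), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()),
           envir = streams$states)
    .restore_rng_state(old)
  })
  expr
}
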