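# Run artifacts: config hashing, angle archives, score tables and the run
# manifest. Every artifact starts with a comment header carrying the config
# hash so mixed inputs can be refused downstream. Manifests carry no
# wall-clock information: identical seed + config reruns are byte-identical.

# small polynomial rolling hash (stable identity tag; not cryptographic)
.poly_hash <- function(s) {
  p <- 134217689
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% p
  sprintf("%08x", as.integer(h))
}

#' Configuration hash
#'
#' Deterministic tag of a flat configuration list, used to stamp artifacts
#' and refuse mixed-run inputs in analysis.
#'
#' @param config named list of scalar configuration values.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  config <- config[order(names(config))]
  .poly_hash(paste(names(config),
                   vapply(config, function(v) paste(format(v), collapse = ","),
                          ""),
                   sep = "=", collapse = ";"))
}

#' Write a decoy run to an output directory
#'
#' Emits the angle archive (\code{angles.tsv}: one row per decoy with
#' generation, lineage and all 3n angles), the score table
#' (\code{scores.tsv}), the per-generation log (\code{generations.tsv}) and
#' the run manifest (\code{manifest.json}). All files begin with the config
#' hash; given the same seed and configuration the archives are
#' byte-identical across reruns.
#'
#' @param run a \code{decoy_run}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run_archive <- function(run, dir) {
  stopifnot(inherits(run, "decoy_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- run$config_hash
  ens <- run$ensemble
  n <- length(ens$sequence)

  hdr <- sprintf("# evodecoy %%s v1 hash=%s seed=%d n=%d", hash,
                 run$config$seed, n)
  apath <- file.path(dir, "angles.tsv")
  con <- file(apath, "w")
  writeLines(sprintf(hdr, "angles"), con)
  writeLines(paste(c("decoy", "generation", "member_id", "parent_id",
                     paste0("a", seq_len(3L * n))), collapse = "\t"), con)
  m <- ens$meta
  body <- paste(m$decoy, m$generation, m$member_id,
                ifelse(is.na(m$parent_id), "NA", m$parent_id),
                apply(ens$angles, 1L, function(r)
                  paste(sprintf("%.6f", r), collapse = "\t")),
                sep = "\t")
  writeLines(body, con)
  close(con)

  spath <- file.path(dir, "scores.tsv")
  con <- file(spath, "w")
  writeLines(sprintf(hdr, "scores"), con)
  writeLines(paste(c("decoy", "generation", "member_id", "parent_id",
                     "energy"), collapse = "\t"), con)
  writeLines(paste(m$decoy, m$generation, m$member_id,
                   ifelse(is.na(m$parent_id), "NA", m$parent_id),
                   sprintf("%.9g", m$energy), sep = "\t"), con)
  close(con)

  gpath <- file.path(dir, "generations.tsv")
  con <- file(gpath, "w")
  writeLines(sprintf(hdr, "generations"), con)
  lg <- run$logs
  writeLines(paste(names(lg), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(lg, function(col)
    if (is.numeric(col)) sprintf("%.9g", col) else format(col)),
    sep = "\t")), con)
  close(con)

  manifest <- list(tool = "evodecoy",
                   version = as.character(utils::packageVersion("evodecoy")),
                   config = run$config, config_hash = hash,
                   eval_count = run$eval_count,
                   generations = run$generations,
                   sequence = paste(ens$sequence, collapse = ""),
                   files = list(angles = "angles.tsv", scores = "scores.tsv",
                                generations = "generations.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

.archive_hash <- function(path) {
  first <- readLines(path, n = 1L)
  sub(".*hash=([0-9a-f]+).*", "\\1", first)
}

#' Read a decoy run archive
#'
#' Reconstructs the decoy ensemble and logs written by
#' \code{\link{write_run_archive}}.
#'
#' @param dir archive directory.
#' @return list with \code{ensemble}, \code{logs}, \code{manifest} and
#'   \code{config_hash}.
#' @export
read_run_archive <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  apath <- file.path(dir, "angles.tsv")
  hash <- .archive_hash(apath)
  tab <- utils::read.table(apath, header = TRUE, sep = "\t", comment.char = "#")
  n <- nchar(man$sequence)
  ang <- as.matrix(tab[, -(1:4), drop = FALSE])
  dimnames(ang) <- NULL
  sc <- utils::read.table(file.path(dir, "scores.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
  meta <- data.frame(decoy = tab$decoy, generation = tab$generation,
                     member_id = tab$member_id, parent_id = tab$parent_id,
                     energy = sc$energy)
  lg <- utils::read.table(file.path(dir, "generations.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
  ens <- decoy_ensemble(strsplit(man$sequence, "")[[1L]], ang, meta)
  list(ensemble = ens, logs = lg, manifest = man, config_hash = hash)
}

#' Read a flat JSON run configuration
#'
#' @param path JSON file with a flat key set (pop_size, num_child, eval_max,
#'   seed, algorithm, ...). Command-line flags override file values.
#' @return named list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
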