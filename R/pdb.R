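# PDB backbone input/output. Reading goes through bio3d; writing emits
# standard ATOM records, with MODEL/ENDMDL blocks for decoy sets.

.AA321 <- stats::setNames(names(.AA3), .AA3)

#' Read backbone atoms from a PDB file
#'
#' Extracts N, CA, C, O and CB for one chain of one model. Alternate
#' locations other than 'A' are discarded; residues with incomplete N/CA/C
#' are dropped with a warning; the sequence is derived from residue names.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default the first chain in the file.
#' @param model model number for multi-model files (default 1).
#' @return list with \code{sequence} (one-letter codes), \code{coords}
#'   (a \code{backbone_coords}) and \code{resno} (author residue numbers).
#' @export
read_pdb_backbone <- function(path, chain = NULL, model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmodels <- nrow(pdb$xyz)
  if (model < 1L || model > nmodels)
    stop("model ", model, " not present (file has ", nmodels, ")")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  if (is.null(chain)) chain <- at$chain[1L]
  sel <- which(at$chain == chain & at$elety %in% c("N", "CA", "C", "O", "CB"))
  if (!length(sel)) stop("no backbone atoms for chain '", chain, "' in ", path)
  at <- at[sel, , drop = FALSE]
  xyz <- xyz[sel, , drop = FALSE]

  resnos <- unique(at$resno)
  keep <- character(0)
  seq1 <- character(0)
  rows <- list()
  dropped <- integer(0)
  for (rn in resnos) {
    ri <- which(at$resno == rn)
    have <- at$elety[ri]
    if (!all(c("N", "CA", "C") %in% have)) {
      dropped <- c(dropped, rn)
      next
    }
    res3 <- at$resid[ri[1L]]
    aa <- .AA321[res3]
    if (is.na(aa)) {
      dropped <- c(dropped, rn)
      next
    }
    seq1 <- c(seq1, unname(aa))
    keep <- c(keep, rn)
    rows[[length(rows) + 1L]] <- vapply(
      c("N", "CA", "C", "O", "CB"), function(a) {
        k <- ri[match(a, at$elety[ri])]
        if (is.na(k)) rep(NA_real_, 3L) else xyz[k, ]
      }, numeric(3L))
  }
  if (!length(rows))
    stop("no complete backbone residues in ", path)
  if (length(dropped))
    warning("dropped ", length(dropped),
            " residue(s) with incomplete backbone or nonstandard name: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  n <- length(rows)
  co <- list(sequence = seq1)
  for (k in seq_along(c("N", "CA", "C", "O", "CB"))) {
    a <- c("N", "CA", "C", "O", "CB")[k]
    co[[a]] <- t(vapply(rows, function(m) m[, a], numeric(3L)))
  }
  gly <- seq1 == "G"
  co$CB[gly, ] <- NA_real_
  class(co) <- "backbone_coords"
  list(sequence = seq1, coords = co, resno = as.integer(keep))
}

.pdb_atom_line <- function(serial, name, res3, chain, resno, xyz) {
  name4 <- sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, res3, chain, resno, xyz[1L], xyz[2L], xyz[3L],
          1, 0, substr(name, 1L, 1L))
}

.write_one_model <- function(con, coords, chain, serial0 = 0L) {
  seq1 <- coords$sequence
  serial <- serial0
  for (i in seq_along(seq1)) {
    res3 <- .AA3[seq1[i]]
    for (a in c("N", "CA", "C", "O", "CB")) {
      xyz <- coords[[a]][i, ]
      if (any(!is.finite(xyz))) next
      serial <- serial + 1L
      writeLines(.pdb_atom_line(serial, a, res3, chain, i, xyz), con)
    }
  }
  writeLines(sprintf("TER   %5d      %3s %1s%4d",
                     serial + 1L, .AA3[seq1[length(seq1)]], chain,
                     length(seq1)), con)
  serial + 1L
}

#' Write conformations to a PDB file
#'
#' A single conformation is written as plain ATOM records; a list of decoys
#' as MODEL/ENDMDL blocks. Residue numbering is 1-based; coordinates are
#' written to 3 decimals.
#'
#' @param x a \code{conformation}, \code{backbone_coords}, or list of either.
#' @param path output file path.
#' @param chain chain identifier to write (default "A").
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(x, path, chain = "A") {
  models <- if (inherits(x, c("conformation", "backbone_coords"))) list(x)
  else x
  models <- lapply(models, function(m)
    if (inherits(m, "conformation")) coordinates(m) else m)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(models) == 1L) {
    .write_one_model(con, models[[1L]], chain)
  } else {
    for (k in seq_along(models)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      .write_one_model(con, models[[k]], chain)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an amino-acid sequence from FASTA
#'
#' @param path FASTA file path.
#' @param i record index when the file holds several (default 1).
#' @return character vector of one-letter codes.
#' @export
read_fasta_sequence <- function(path, i = 1L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", seqonly = FALSE)
  if (i > length(recs)) stop("FASTA record ", i, " not present in ", path)
  .check_sequence(toupper(as.character(recs[[i]])))
}

#' Write an amino-acid sequence as FASTA
#'
#' @param sequence one-letter codes.
#' @param path output path.
#' @param name record name.
#' @return \code{path}, invisibly.
#' @export
write_fasta_sequence <- function(sequence, path, name = "target") {
  sequence <- .check_sequence(sequence)
  writeLines(c(paste0(">", name), paste(sequence, collapse = "")), path)
  invisible(path)
}
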