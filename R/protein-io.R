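# Input handling: PDB and FASTA files are parsed into ProteinModel objects,
# the container every downstream index, grouping and descriptor routine
# consumes.

#' Construct a ProteinModel
#'
#' A `ProteinModel` is an ordered list of residues, optionally carrying atomic
#' coordinates, secondary-structure labels and relative solvent
#' accessibilities.  Positions are always 1..N in model order; the original
#' PDB residue numbers are retained as metadata only.
#'
#' @param id protein identifier.
#' @param residues data frame with columns `position` (1..N), `aa`
#'   (three-letter code), `resseq` (original PDB numbering or NA), `ss`
#'   (`"HELIX"`, `"SHEET"`, `"TURN"`, `"COIL"` or NA) and `rel_sasa`
#'   (fraction in \[0,1\] or NA).
#' @param atoms data frame of atomic coordinates with columns `position`,
#'   `atom`, `x`, `y`, `z`, `element`, or `NULL` for sequence-only models.
#' @param source_format `"PDB"` or `"FASTA"`.
#' @return An object of class `ProteinModel`.
#' @export
new_protein_model <- function(id, residues, atoms = NULL,
                              source_format = c("PDB", "FASTA")) {
  source_format <- match.arg(source_format)
  stopifnot(is.data.frame(residues), nrow(residues) >= 1L)
  residues$position <- seq_len(nrow(residues))
  if (!all(residues$aa %in% AA3))
    stop("non-standard residue type in model: ",
         paste(setdiff(residues$aa, AA3), collapse = ", "))
  has_structure <- !is.null(atoms) && nrow(atoms) > 0L
  if (!has_structure) {
    residues$ss <- NA_character_
    residues$rel_sasa <- NA_real_
    atoms <- NULL
  }
  structure(
    list(id = id, residues = residues, atoms = atoms,
         has_structure = has_structure, source_format = source_format),
    class = "ProteinModel"
  )
}

#' @export
print.ProteinModel <- function(x, ...) {
  cat(sprintf("ProteinModel '%s': %d residues, %s (%s)\n",
              x$id, n_residues(x),
              if (x$has_structure) "with structure" else "sequence only",
              x$source_format))
  cat(" sequence: ", model_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a model
#' @param model a [ProteinModel][new_protein_model].
#' @export
n_residues <- function(model) nrow(model$residues)

#' One-letter sequence of a model
#' @inheritParams n_residues
#' @export
model_sequence <- function(model) paste(.aa_one(model$residues$aa),
                                        collapse = "")

#' C-alpha coordinate matrix
#'
#' Returns an N x 3 matrix of C-alpha coordinates; rows are NA for residues
#' whose CA atom is missing.
#' @inheritParams n_residues
#' @export
ca_coords <- function(model) {
  stop_if_no_structure(model, "ca_coords")
  n <- n_residues(model)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  out[ca$position, ] <- as.matrix(ca[, c("x", "y", "z")])
  out
}

stop_if_no_structure <- function(model, what) {
  if (!isTRUE(model$has_structure))
    stop(sprintf(
      "'%s' requires 3D coordinates; model '%s' is sequence-only",
      what, model$id), call. = FALSE)
  invisible(model)
}

# -- PDB ----------------------------------------------------------------------

# bio3d does not parse (long-obsolete but still emitted) TURN records; read
# them directly.  Columns follow the PDB format: chain id 20, first residue
# 21-24, chain id 31, last residue 32-35.
.read_turn_records <- function(path) {
  lines <- grep("^TURN", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  data.frame(
    chain = substr(lines, 20, 20),
    start = as.integer(substr(lines, 21, 24)),
    end   = as.integer(substr(lines, 32, 35)),
    stringsAsFactors = FALSE
  )
}

.ss_from_ranges <- function(resseq, chain, rec, label, ss) {
  if (is.null(rec) || !length(rec$start)) return(ss)
  for (k in seq_along(rec$start)) {
    ch <- rec$chain[k]
    hit <- resseq >= rec$start[k] & resseq <= rec$end[k] &
      (is.na(ch) | ch == "" | ch == chain)
    ss[hit & ss == "COIL"] <- label
  }
  ss
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (via bio3d) into a structure-bearing
#' [ProteinModel][new_protein_model].  ANISOU, REMARK and hetero records are
#' ignored, except selenomethionine/selenocysteine which are mapped to their
#' standard parents.  HELIX/SHEET/TURN records, when present, provide the
#' secondary-structure labels; no recomputation from geometry is attempted.
#' Alternate locations are resolved by keeping the first conformer.  Residues
#' without a CA atom, and residues of unmappable type, are dropped with a
#' warning.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; default is the first chain in the file.
#' @return A `ProteinModel` with `has_structure = TRUE`.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  keep_type <- at$type == "ATOM" |
    (at$type == "HETATM" & at$resid %in% names(NONSTANDARD_MAP))
  at <- at[keep_type, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records for standard residues in ", path)
  at$chain[is.na(at$chain)] <- ""
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains)
    stop(sprintf("chain '%s' not found in %s (available: %s)",
                 chain, path, paste(chains, collapse = ", ")))
  at <- at[at$chain == chain, , drop = FALSE]

  # first altloc conformer per (residue, atom name)
  at$insert[is.na(at$insert)] <- ""
  rid <- paste(at$resno, at$insert, sep = "|")
  dup <- duplicated(paste(rid, at$elety))
  at <- at[!dup, , drop = FALSE]
  rid <- rid[!dup]

  res_ids <- unique(rid)
  aa <- character(0); resseq <- integer(0)
  atoms <- vector("list", length(res_ids))
  pos <- 0L; dropped <- character(0)
  for (r in res_ids) {
    sub <- at[rid == r, , drop = FALSE]
    type <- sub$resid[1L]
    if (type %in% names(NONSTANDARD_MAP)) type <- NONSTANDARD_MAP[[type]]
    if (!type %in% AA3 || !"CA" %in% sub$elety) {
      dropped <- c(dropped, sprintf("%s%s", sub$resid[1L], r))
      next
    }
    pos <- pos + 1L
    aa[pos] <- type
    resseq[pos] <- sub$resno[1L]
    elem <- sub$elesy
    if (is.null(elem) || all(is.na(elem)))
      elem <- substr(gsub("[0-9]", "", sub$elety), 1, 1)
    atoms[[pos]] <- data.frame(
      position = pos, atom = sub$elety,
      x = sub$x, y = sub$y, z = sub$z,
      element = toupper(ifelse(is.na(elem) | elem == "",
                               substr(sub$elety, 1, 1), elem)),
      stringsAsFactors = FALSE
    )
  }
  if (pos == 0L) stop("no standard residues with CA atoms in ", path)
  if (length(dropped))
    warning(sprintf("dropped %d residue(s) from %s: %s", length(dropped),
                    basename(path), paste(dropped, collapse = ", ")))
  atoms <- do.call(rbind, atoms[seq_len(pos)])

  ss <- rep("COIL", pos)
  ss <- .ss_from_ranges(resseq, chain, pdb$helix, "HELIX", ss)
  ss <- .ss_from_ranges(resseq, chain, pdb$sheet, "SHEET", ss)
  ss <- .ss_from_ranges(resseq, chain, .read_turn_records(path), "TURN", ss)

  residues <- data.frame(
    position = seq_len(pos), aa = aa, resseq = resseq,
    ss = ss, rel_sasa = NA_real_, stringsAsFactors = FALSE
  )
  id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  new_protein_model(id, residues, atoms, source_format = "PDB")
}

# -- FASTA --------------------------------------------------------------------

#' Read protein sequences from a FASTA file
#'
#' Each record becomes a sequence-only [ProteinModel][new_protein_model]
#' (`has_structure = FALSE`); only sequence-based indices and the whole
#' protein group apply to such models.  Lowercase letters are accepted;
#' letters outside the 20 standard residues (X, B, Z, U, O, ...) are dropped
#' with a warning.
#'
#' @param path path to a FASTA or multi-FASTA file.
#' @return A list of `ProteinModel` objects, one per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA file ", path,
                                           ": ", conditionMessage(e)))
  if (!length(set)) stop("no sequence records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    letters1 <- strsplit(toupper(as.character(set[[k]])), "")[[1L]]
    bad <- !(letters1 %in% names(AA3))
    if (any(bad)) {
      warning(sprintf("record '%s': dropped %d non-standard letter(s): %s",
                      ids[k], sum(bad),
                      paste(unique(letters1[bad]), collapse = ", ")))
      letters1 <- letters1[!bad]
    }
    if (!length(letters1))
      stop(sprintf("record '%s' has no standard residues", ids[k]))
    residues <- data.frame(
      position = seq_along(letters1), aa = .aa_three(letters1),
      resseq = NA_integer_, ss = NA_character_, rel_sasa = NA_real_,
      stringsAsFactors = FALSE
    )
    out[[k]] <- new_protein_model(ids[k], residues, NULL,
                                  source_format = "FASTA")
  }
  out
}

#' Read protein inputs of either format
#'
#' Convenience dispatcher used by the project runner and the command line:
#' `.pdb`/`.ent` files go through [read_pdb()], everything else through
#' [read_fasta()].
#'
#' @param paths character vector of input files.
#' @param format `"auto"`, `"pdb"` or `"fasta"`.
#' @param chain optional chain id forwarded to [read_pdb()].
#' @return A list of `ProteinModel` objects.
#' @export
read_proteins <- function(paths, format = c("auto", "pdb", "fasta"),
                          chain = NULL) {
  format <- match.arg(format)
  out <- list()
  for (p in paths) {
    fmt <- format
    if (fmt == "auto")
      fmt <- if (grepl("\\.(pdb|ent)$", p, ignore.case = TRUE)) "pdb"
             else "fasta"
    out <- c(out, if (fmt == "pdb") list(read_pdb(p, chain = chain))
                  else read_fasta(p))
  }
  out
}
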