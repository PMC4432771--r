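# Residue groups: the subsets of positions over which index values are
# aggregated into descriptors.  Three families: by amino-acid type, by
# physicochemical class, and by structural context (burial and secondary
# structure), plus the whole protein (PRT).

#' Construct a ResidueGroup
#'
#' @param name group name (amino-acid code, class name, or structural tag).
#' @param members integer positions, strictly increasing subset of 1..N;
#'   may be empty.
#' @return An object of class `ResidueGroup`.
#' @export
residue_group <- function(name, members = integer(0)) {
  members <- sort(unique(as.integer(members)))
  structure(list(name = name, members = members), class = "ResidueGroup")
}

#' @export
print.ResidueGroup <- function(x, ...) {
  cat(sprintf("ResidueGroup %s: %d residue(s)\n", x$name,
              length(x$members)))
  invisible(x)
}

#' Amino-acid type groups
#'
#' Exactly 20 groups, one per standard amino acid (named by three-letter
#' code), forming a partition of the residues; empty groups are kept so the
#' descriptor table stays rectangular across proteins.
#'
#' @param model a [ProteinModel][new_protein_model].
#' @return Named list of 20 [residue_group()] objects.
#' @export
type_groups <- function(model) {
  out <- lapply(unname(AA3), function(a)
    residue_group(a, which(model$residues$aa == a)))
  names(out) <- unname(AA3)
  out
}

#' Physicochemical class groups
#'
#' Groups per the bundled classification (polar, nonpolar, basic, acidic,
#' aromatic, aliphatic, charged, tiny, small).  Histidine belongs to both
#' the basic and the aromatic class; charged is the union of basic and
#' acidic.
#'
#' @inheritParams type_groups
#' @return Named list of [residue_group()] objects.
#' @export
property_groups <- function(model) {
  aa1 <- .aa_one(model$residues$aa)
  out <- lapply(names(PROPERTY_CLASSES), function(cl)
    residue_group(cl, which(aa1 %in% PROPERTY_CLASSES[[cl]])))
  names(out) <- names(PROPERTY_CLASSES)
  out
}

#' Structure-based groups
#'
#' \describe{
#'   \item{PRT}{all residues (also the only group available to
#'     sequence-only models).}
#'   \item{INT / SUP}{buried (`rel_sasa < sasa_cutoff`) and superficial
#'     residues; a partition of PRT at the cutoff.}
#'   \item{HEX / SHT / TRN}{residues labelled HELIX / SHEET / TURN by the
#'     PDB secondary-structure records.}
#'   \item{RCL}{coil: every residue in neither helix nor sheet (turns are
#'     coil by this definition).}
#' }
#'
#' @inheritParams type_groups
#' @param sasa_cutoff relative accessibility below which a residue counts
#'   as internal (default 0.25).
#' @return Named list of [residue_group()] objects.
#' @export
structure_groups <- function(model, sasa_cutoff = 0.25) {
  stop_if_no_structure(model, "structure_groups")
  rs <- model$residues$rel_sasa
  if (anyNA(rs))
    stop("rel_sasa not computed; run compute_sasa() before ",
         "structure_groups()")
  ss <- model$residues$ss
  n <- n_residues(model)
  list(
    PRT = residue_group("PRT", seq_len(n)),
    INT = residue_group("INT", which(rs < sasa_cutoff)),
    SUP = residue_group("SUP", which(rs >= sasa_cutoff)),
    HEX = residue_group("HEX", which(ss == "HELIX")),
    SHT = residue_group("SHT", which(ss == "SHEET")),
    TRN = residue_group("TRN", which(ss == "TURN")),
    RCL = residue_group("RCL", which(!ss %in% c("HELIX", "SHEET")))
  )
}

#' Resolve residue groups by name
#'
#' Engine-facing helper: maps group names (`"PRT"`, structural tags, class
#' names, or amino-acid three-letter codes) onto [residue_group()] objects
#' for one model.  Structural groups on a sequence-only model resolve to
#' `NULL` (the engine emits sentinel columns for them).
#'
#' @inheritParams type_groups
#' @param names character vector of group names.
#' @param sasa_cutoff forwarded to [structure_groups()].
#' @return Named list; entries are `ResidueGroup` or `NULL` when a
#'   structural group is unavailable for the model.
#' @export
resolve_groups <- function(model, names, sasa_cutoff = 0.25) {
  structural <- c("INT", "SUP", "HEX", "SHT", "TRN", "RCL")
  tg <- NULL; pg <- NULL; sg <- NULL
  out <- vector("list", length(names))
  names(out) <- names
  for (nm in names) {
    if (nm == "PRT") {
      out[[nm]] <- residue_group("PRT", seq_len(n_residues(model)))
    } else if (nm %in% structural) {
      if (!model$has_structure) { out[nm] <- list(NULL); next }
      if (is.null(sg)) sg <- structure_groups(model, sasa_cutoff)
      out[[nm]] <- sg[[nm]]
    } else if (nm %in% AA3) {
      if (is.null(tg)) tg <- type_groups(model)
      out[[nm]] <- tg[[nm]]
    } else if (nm %in% names(PROPERTY_CLASSES)) {
      if (is.null(pg)) pg <- property_groups(model)
      out[[nm]] <- pg[[nm]]
    } else {
      stop("unknown residue group '", nm, "'")
    }
  }
  out
}
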