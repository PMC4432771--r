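# The four-level combinatorial engine: index x weighting x group x
# aggregator.  Descriptor names follow the frozen grammar
#   <index>[_<weightop><k>]_<group>_<aggregator>     e.g. HP_PRT_Q2,
#   wCO_AC2_INT_SD
# and the column count is always |indices| x |weightings| x |groups| x
# |aggregators|: incompatible selections (structure index on a sequence-only
# model, empty group) fill with the missing-value sentinel instead of
# dropping columns.

#' Compute one named per-residue index
#'
#' Dispatches on the index family: registered property scales (sequence
#' capable), topographic contact indices (`wCO`, `wLRO`, `wTCD`, `wNc`,
#' `wCLQ`, `lnFD`) and thermodynamic-style indices (`Ele`, `Vdw`, `HBd`,
#' `Tor`, `Hph`, `HphS`, `ChgS`).
#'
#' @param model a [ProteinModel][new_protein_model].
#' @param name index name.
#' @param d,t contact-map cutoffs for topographic indices.
#' @param contact_weight contact weighting scheme (see
#'   [build_contact_map()]).
#' @param zero_on_degenerate emit zeros instead of erroring on a contact
#'   map without contacts.
#' @return An [IndexVector][new_index_vector].
#' @export
compute_index <- function(model, name, d = 8, t = 4,
                          contact_weight = "none",
                          zero_on_degenerate = FALSE) {
  if (name %in% TOPOGRAPHIC_INDICES) {
    if (name == "lnFD") return(lnfd_index(model))
    cm <- build_contact_map(model, d_cut = d, t_cut = t,
                            weight_scheme = contact_weight)
    return(topographic_index(model, cm, name,
                             zero_on_degenerate = zero_on_degenerate))
  }
  if (name %in% THERMODYNAMIC_INDICES)
    return(thermodynamic_index(model, name))
  property_index(model, name)
}

#' Does an index require 3D structure?
#' @param name index name.
#' @return Logical scalar.
#' @export
index_needs_structure <- function(name) {
  if (name %in% TOPOGRAPHIC_INDICES) return(TRUE)
  if (name %in% THERMODYNAMIC_INDICES)
    return(unname(.thermo_needs_structure[name]))
  FALSE
}

#' Construct a DescriptorTable
#'
#' @param values numeric matrix, proteins x descriptors (NA = sentinel).
#' @param protein_ids,descriptor_names dimension names.
#' @return Object of class `DescriptorTable` (a matrix with dimnames).
#' @export
descriptor_table <- function(values, protein_ids, descriptor_names) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(protein_ids),
            ncol(values) == length(descriptor_names),
            !anyDuplicated(descriptor_names))
  dimnames(values) <- list(protein_ids, descriptor_names)
  class(values) <- c("DescriptorTable", class(values))
  values
}

#' @export
print.DescriptorTable <- function(x, ...) {
  cat(sprintf("DescriptorTable: %d protein(s) x %d descriptor(s)\n",
              nrow(x), ncol(x)))
  if (ncol(x) <= 8 && nrow(x) <= 10) print(unclass(x)) else {
    cat(" first descriptors:",
        paste(utils::head(colnames(x), 5), collapse = ", "), "...\n")
  }
  invisible(x)
}

#' Generate the full descriptor set for a list of proteins
#'
#' Runs the four-level pipeline.  For every protein each selected index is
#' computed, transformed by every selected weighting operator, restricted to
#' every selected group, and collapsed by every selected aggregator.
#'
#' @param models list of [ProteinModel][new_protein_model]s.
#' @param cfg a [project_config()].
#' @return A list with `residue_tables` (per protein, residues x weighted
#'   indices matrix with labelled rows) and `table` (the
#'   [descriptor_table()]).
#' @export
generate_descriptors <- function(models, cfg) {
  stopifnot(length(models) >= 1L)
  cfg <- validate_config(cfg)
  idx <- cfg$indices; wts <- cfg$weightings
  grps <- cfg$groups; aggs <- cfg$aggregators

  specs <- lapply(wts, parse_weighting)
  tags <- vapply(specs, weighting_tag, "")
  iw_names <- as.vector(t(outer(idx, tags, function(a, b)
    ifelse(nzchar(b), paste(a, b, sep = "_"), a))))

  desc_names <- character(0)
  for (i in idx) for (tg in tags) {
    stem <- if (nzchar(tg)) paste(i, tg, sep = "_") else i
    for (g in grps) for (a in aggs)
      desc_names <- c(desc_names, paste(stem, g, a, sep = "_"))
  }

  values <- matrix(NA_real_, length(models), length(desc_names))
  residue_tables <- vector("list", length(models))
  ids <- vapply(models, function(m) m$id, "")

  needs_sasa <- any(c("Hph") %in% idx) ||
    any(c("INT", "SUP") %in% grps)

  for (m in seq_along(models)) {
    model <- models[[m]]
    if (model$has_structure && needs_sasa &&
        anyNA(model$residues$rel_sasa))
      model <- compute_sasa(model, probe_radius = cfg$probe_radius)

    n <- n_residues(model)
    rt <- matrix(NA_real_, n, length(iw_names),
                 dimnames = list(residue_labels(model), iw_names))
    groups <- resolve_groups(model, grps, sasa_cutoff = cfg$sasa_cutoff)

    col <- 0L
    for (i in idx) {
      incapable <- !model$has_structure && index_needs_structure(i)
      if (incapable && cfg$strict)
        stop(sprintf("index '%s' requires structure but model '%s' is %s",
                     i, model$id, "sequence-only (strict mode)"))
      iv <- if (incapable) NULL else
        compute_index(model, i, d = cfg$d, t = cfg$t,
                      contact_weight = cfg$contact_weight,
                      zero_on_degenerate = cfg$zero_on_degenerate)
      for (s in seq_along(specs)) {
        wv <- if (is.null(iv)) NULL else
          .iv_values(apply_weighting(iv, specs[[s]]))
        stem_col <- (match(i, idx) - 1L) * length(tags) + s
        if (!is.null(wv)) rt[, stem_col] <- wv
        for (g in grps) {
          grp <- groups[[g]]
          for (a in aggs) {
            col <- col + 1L
            if (!is.null(wv) && !is.null(grp) && length(grp$members))
              values[m, col] <- aggregate_values(wv[grp$members], a,
                                                 precision = cfg$ic_precision)
          }
        }
      }
    }
    residue_tables[[m]] <- rt
    if (any(is.na(values[m, ])))
      message(sprintf(
        "protein '%s': %d of %d descriptor(s) carry the missing sentinel",
        model$id, sum(is.na(values[m, ])), length(desc_names)))
  }
  list(residue_tables = residue_tables,
       table = descriptor_table(values, ids, desc_names))
}

#' Residue row labels in output files
#'
#' Style `<proteinID>_aa<position>_<TYPE>`, e.g. `1OEH_aa1_HIS`.
#' @inheritParams n_residues
#' @return Character vector of length N.
#' @export
residue_labels <- function(model) {
  sprintf("%s_aa%d_%s", model$id, model$residues$position,
          model$residues$aa)
}

.fmt_num <- function(x, sentinel = "NA") {
  out <- sprintf("%.6E", x)
  out[is.na(x)] <- sentinel
  out
}

#' Write the residue-level and protein-level output files
#'
#' Produces the two tab-delimited products: `<prefix>_AA.txt` (rows =
#' residues of all proteins, labelled `<id>_aa<pos>_<TYPE>`; columns = the
#' weighted per-residue indices) and `<prefix>_Prot.txt` (rows = proteins,
#' columns = descriptors).  Numbers are written in scientific notation with
#' 6 significant decimals so re-runs are byte-identical.
#'
#' @param residue_tables,table the two components returned by
#'   [generate_descriptors()].
#' @param prefix output path prefix.
#' @param sentinel token written for missing values.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_outputs <- function(residue_tables, table, prefix, sentinel = "NA") {
  stopifnot(length(residue_tables) >= 1L, nrow(table) >= 1L)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  aa_path <- paste0(prefix, "_AA.txt")
  prot_path <- paste0(prefix, "_Prot.txt")

  rt <- do.call(rbind, residue_tables)
  aa_lines <- c(
    paste(c("Residue", colnames(rt)), collapse = "\t"),
    vapply(seq_len(nrow(rt)), function(r)
      paste(c(rownames(rt)[r], .fmt_num(rt[r, ], sentinel)),
            collapse = "\t"), "")
  )
  writeLines(aa_lines, aa_path)

  prot_lines <- c(
    paste(c("Protein", colnames(table)), collapse = "\t"),
    vapply(seq_len(nrow(table)), function(r)
      paste(c(rownames(table)[r], .fmt_num(table[r, ], sentinel)),
            collapse = "\t"), "")
  )
  writeLines(prot_lines, prot_path)
  invisible(c(aa_path, prot_path))
}

#' Read a protein-level descriptor table back from disk
#'
#' Inverse of the `_Prot.txt` writer; sentinel tokens become NA.
#'
#' @param path path to a `*_Prot.txt` file.
#' @param sentinel missing-value token used when the file was written.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, sentinel = "NA") {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE,
                           na.strings = sentinel)
  descriptor_table(as.matrix(tab), rownames(tab), colnames(tab))
}
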