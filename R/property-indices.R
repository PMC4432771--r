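# Property-based per-residue indices: pure lookups into amino-acid scales,
# plus a run-time registry so user tables (e.g. the 147 electron-density
# derived residue scales distributed with some descriptor suites) can be
# loaded from plain tab-delimited files.

.scale_registry <- new.env(parent = emptyenv())

.registry_scales <- function() {
  user <- if (length(ls(.scale_registry))) {
    do.call(cbind, mget(ls(.scale_registry), envir = .scale_registry))
  } else NULL
  if (is.null(user)) BUILTIN_SCALES else cbind(BUILTIN_SCALES, user)
}

#' List registered property scales
#' @return Character vector of scale names (built-in plus user-registered).
#' @export
list_property_scales <- function() colnames(.registry_scales())

#' Register user property scales
#'
#' @param scales a numeric matrix or data frame with one row per amino acid
#'   (rownames: one- or three-letter codes, any case) and one column per
#'   scale; all 20 standard residues must be covered.
#' @return Invisibly, the names of the newly registered scales.
#' @export
register_property_scales <- function(scales) {
  scales <- as.matrix(scales)
  rn <- toupper(rownames(scales))
  if (is.null(rn)) stop("property table needs amino-acid rownames")
  one <- ifelse(nchar(rn) == 3L, .aa_one(rn), rn)
  if (anyNA(one) || !all(names(AA3) %in% one))
    stop("property table must cover all 20 standard amino acids")
  scales <- scales[match(names(AA3), one), , drop = FALSE]
  rownames(scales) <- names(AA3)
  storage.mode(scales) <- "double"
  if (anyNA(scales)) stop("property table contains missing values")
  for (nm in colnames(scales))
    assign(nm, scales[, nm, drop = FALSE], envir = .scale_registry)
  invisible(colnames(scales))
}

#' Load property scales from a tab-delimited file
#'
#' Expected layout: a header row of scale names, then one row per amino acid
#' whose first column is the one- or three-letter code.
#'
#' @param path path to the table.
#' @return Invisibly, the registered scale names.
#' @export
load_property_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  register_property_scales(tab)
}

#' Clear user-registered property scales
#' @export
clear_property_scales <- function() {
  rm(list = ls(.scale_registry), envir = .scale_registry)
  invisible(NULL)
}

#' Property-scale per-residue index
#'
#' A pure lookup: residue i gets the scale value of its amino-acid type.
#' Works on sequence-only models.
#'
#' @param model a [ProteinModel][new_protein_model].
#' @param scale a registered scale name; see [list_property_scales()].
#' @return An [IndexVector][new_index_vector].
#' @export
property_index <- function(model, scale) {
  tab <- .registry_scales()
  if (!scale %in% colnames(tab))
    stop("unknown property scale '", scale, "'; registered scales: ",
         paste(colnames(tab), collapse = ", "))
  vals <- tab[.aa_one(model$residues$aa), scale]
  new_index_vector(model$id, scale, unname(vals))
}

# -- thermodynamic-style indices ----------------------------------------------

# The energy-like family.  Each member is a documented closed form chosen by
# this package (favourable contributions negative, kcal/mol-like scale) and
# is registered in a table so alternative definitions can be plugged in
# without touching callers.

THERMODYNAMIC_INDICES <- c("Ele", "Vdw", "HBd", "Tor", "Hph",
                           "HphS", "ChgS")

.thermo_needs_structure <- c(Ele = TRUE, Vdw = TRUE, HBd = TRUE,
                             Tor = TRUE, Hph = TRUE,
                             HphS = FALSE, ChgS = FALSE)

#' Thermodynamic-style per-residue indices
#'
#' Energy-like contributions per residue:
#' \describe{
#'   \item{Ele}{screened Coulomb term over charged side chains (CA
#'     positions): `E_i = (332/2) sum_j q_i q_j exp(-r_ij/lambda)/r_ij`,
#'     `lambda` = 10 A.}
#'   \item{Vdw}{half-share of a 12-6 Lennard-Jones sum over CA pairs with
#'     per-type radii derived from residue mass, `|i-j| > 2`.}
#'   \item{HBd}{-0.75 per backbone hydrogen bond the residue takes part in
#'     (N...O < 3.5 A, `|i-j| >= 3`); all zero when backbone N/O atoms are
#'     absent.}
#'   \item{Tor}{3-fold torsion potential `-(cos 3 phi + cos 3 psi)/2`;
#'     missing dihedrals contribute 0.}
#'   \item{Hph}{hydrophobic burial: Kyte-Doolittle value times the buried
#'     fraction `(1 - rel_sasa)`; requires [compute_sasa()] first.}
#'   \item{HphS}{sequence-only analogue: the bare hydrophobicity value
#'     (full burial reference state).}
#'   \item{ChgS}{sequence-only analogue: formal side-chain charge.}
#' }
#'
#' @param model a [ProteinModel][new_protein_model]; structure-based members
#'   (`Ele`, `Vdw`, `HBd`, `Tor`, `Hph`) error on sequence-only models.
#' @param name index name.
#' @return An [IndexVector][new_index_vector].
#' @export
thermodynamic_index <- function(model, name) {
  if (!name %in% THERMODYNAMIC_INDICES)
    stop("unknown thermodynamic index '", name, "'; supported: ",
         paste(THERMODYNAMIC_INDICES, collapse = ", "))
  if (.thermo_needs_structure[[name]])
    stop_if_no_structure(model, paste0("thermodynamic index ", name))
  aa1 <- .aa_one(model$residues$aa)
  n <- n_residues(model)
  vals <- switch(name,
    HphS = unname(BUILTIN_SCALES[aa1, "HP"]),
    ChgS = unname(AA_CHARGE[aa1]),
    Ele = {
      q <- AA_CHARGE[aa1]
      dm <- as.matrix(stats::dist(ca_coords(model)))
      scr <- exp(-dm / 10) / dm
      scr[!is.finite(scr)] <- 0
      as.numeric(332 / 2 * q * (scr %*% q))
    },
    Vdw = {
      sigma <- 4.0 * (BUILTIN_SCALES[aa1, "Mw"] / 110)^(1 / 3)
      sij <- outer(sigma, sigma, function(a, b) (a + b) / 2)
      dm <- as.matrix(stats::dist(ca_coords(model)))
      sep <- abs(outer(seq_len(n), seq_len(n), `-`))
      ok <- sep > 2 & is.finite(dm) & dm > 0
      r6 <- (sij / dm)^6
      e <- 4 * 0.2 * (r6^2 - r6)
      e[!ok] <- 0
      unname(rowSums(e) / 2)
    },
    HBd = {
      at <- model$atoms
      Nn <- at[at$atom == "N", , drop = FALSE]
      Oo <- at[at$atom == "O", , drop = FALSE]
      v <- numeric(n)
      if (nrow(Nn) && nrow(Oo)) {
        for (a in seq_len(nrow(Nn))) for (b in seq_len(nrow(Oo))) {
          i <- Nn$position[a]; j <- Oo$position[b]
          if (abs(i - j) < 3) next
          r <- sqrt((Nn$x[a] - Oo$x[b])^2 + (Nn$y[a] - Oo$y[b])^2 +
                      (Nn$z[a] - Oo$z[b])^2)
          if (r < 3.5) { v[i] <- v[i] - 0.75; v[j] <- v[j] - 0.75 }
        }
      }
      v
    },
    Tor = {
      dih <- backbone_dihedrals(model)
      cphi <- ifelse(is.na(dih[, "phi"]), 0, cos(3 * dih[, "phi"]))
      cpsi <- ifelse(is.na(dih[, "psi"]), 0, cos(3 * dih[, "psi"]))
      -(cphi + cpsi) / 2
    },
    Hph = {
      if (anyNA(model$residues$rel_sasa))
        stop("Hph requires rel_sasa; run compute_sasa() first")
      unname(BUILTIN_SCALES[aa1, "HP"] * (1 - model$residues$rel_sasa))
    }
  )
  new_index_vector(model$id, name, vals)
}
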