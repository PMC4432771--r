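# Residue-residue contact maps and the topographic (contact-based) indices.
#
# A pair (i,j) is a contact when its spatial distance is below d_cut AND its
# sequence separation |i-j| exceeds t_cut (defaults d=8 A, t=4).  Each
# contact carries a weight omega_ij: 1 (none), the sequence separation
# |i-j|, or the product of a per-residue property value for the two partners.
# Whole-protein indices originally defined as sums over contacts (contact
# order, long-range order, total contact distance, contact number,
# cliquishness) are redefined per residue so that summing the residue
# contributions recovers the original whole-protein value.

#' Build a residue contact map
#'
#' @param model a structure-bearing [ProteinModel][new_protein_model].
#' @param d_cut spatial cutoff in Angstrom (default 8).
#' @param t_cut minimum sequence separation, exclusive (default 4: contacts
#'   require |i-j| > 4).
#' @param weight_scheme `"none"` (omega = 1), `"seq_separation"`
#'   (omega = |i-j|) or `"property:<scale>"` (omega = product of the scale
#'   values of the two residues, e.g. `"property:HP"`).
#' @param atom_mode atom pair used for the spatial distance: `"ca"`
#'   (C-alpha, default), `"cb"` (C-beta, falling back to CA for glycine or
#'   when absent) or `"heavy_min"` (minimum over all heavy-atom pairs).
#' @return An object of class `ContactMap` with fields `n`, `d_cut`, `t_cut`,
#'   `delta` (logical symmetric matrix), `n_contacts`, `omega` (numeric
#'   symmetric matrix) and `scheme`.
#' @export
build_contact_map <- function(model, d_cut = 8, t_cut = 4,
                              weight_scheme = "none",
                              atom_mode = c("ca", "cb", "heavy_min")) {
  stop_if_no_structure(model, "build_contact_map")
  atom_mode <- match.arg(atom_mode)
  stopifnot(d_cut > 0, t_cut >= 0)
  n <- n_residues(model)

  dm <- .residue_distances(model, atom_mode)
  missing_ca <- which(apply(is.na(dm) | row(dm) == col(dm), 1, all))
  if (length(missing_ca))
    warning(sprintf(
      "%d residue(s) without usable coordinates take part in no contacts",
      length(missing_ca)))

  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  delta <- !is.na(dm) & dm < d_cut & sep > t_cut
  diag(delta) <- FALSE
  delta <- delta & t(delta)

  omega <- .contact_weights(model, weight_scheme, sep, n)

  structure(
    list(n = n, d_cut = d_cut, t_cut = t_cut, delta = delta,
         n_contacts = sum(delta) / 2L, omega = omega,
         scheme = weight_scheme),
    class = "ContactMap"
  )
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf(
    "ContactMap: N=%d, d<%g A, |i-j|>%d, %d contacts, weighting '%s'\n",
    x$n, x$d_cut, x$t_cut, x$n_contacts, x$scheme))
  invisible(x)
}

.residue_distances <- function(model, atom_mode) {
  n <- n_residues(model)
  if (atom_mode == "heavy_min") {
    at <- model$atoms[model$atoms$element != "H", , drop = FALSE]
    xyz <- as.matrix(at[, c("x", "y", "z")])
    dm_at <- as.matrix(stats::dist(xyz))
    dm <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      ai <- which(at$position == i); aj <- which(at$position == j)
      if (length(ai) && length(aj))
        dm[i, j] <- min(dm_at[ai, aj, drop = FALSE])
    }
    return(dm)
  }
  xyz <- ca_coords(model)
  if (atom_mode == "cb") {
    cb <- model$atoms[model$atoms$atom == "CB", , drop = FALSE]
    xyz[cb$position, ] <- as.matrix(cb[, c("x", "y", "z")])
  }
  dm <- as.matrix(stats::dist(xyz))       # rows with NA coords give NA
  dm
}

.contact_weights <- function(model, weight_scheme, sep, n) {
  if (identical(weight_scheme, "none")) {
    matrix(1, n, n)
  } else if (identical(weight_scheme, "seq_separation")) {
    sep * 1.0
  } else if (grepl("^property:", weight_scheme)) {
    scale <- sub("^property:", "", weight_scheme)
    w <- property_index(model, scale)$values
    outer(w, w)
  } else {
    stop("unknown contact weight scheme '", weight_scheme,
         "'; use 'none', 'seq_separation' or 'property:<scale>'")
  }
}

# -- topographic indices ------------------------------------------------------

#' Residue-level weighted contact order
#'
#' For residue i, `wCO_i = (1/(2 N N_c)) * sum_j omega_ij delta_ij`.  With
#' sequence-separation weighting the residue contributions sum to the classic
#' whole-protein relative contact order.
#'
#' @param cm a [ContactMap][build_contact_map].
#' @param protein_id identifier stored in the result.
#' @param zero_on_degenerate if `TRUE`, a map with no contacts yields an
#'   all-zero vector instead of an error.
#' @return An [IndexVector][new_index_vector].
#' @export
weighted_contact_order <- function(cm, protein_id = "protein",
                                   zero_on_degenerate = FALSE) {
  stopifnot(inherits(cm, "ContactMap"))
  if (cm$n_contacts == 0L) {
    if (!zero_on_degenerate)
      stop("contact map has no contacts: weighted contact order undefined ",
           "(set zero_on_degenerate = TRUE to emit zeros)")
    vals <- numeric(cm$n)
  } else {
    vals <- rowSums(cm$omega * cm$delta) / (2 * cm$n * cm$n_contacts)
  }
  new_index_vector(protein_id, "wCO", vals,
                   list(d = cm$d_cut, t = cm$t_cut, scheme = cm$scheme))
}

TOPOGRAPHIC_INDICES <- c("wCO", "wLRO", "wTCD", "wNc", "wCLQ", "lnFD")

#' Topographic per-residue indices
#'
#' Contact-based indices redefined at residue level so that the sum over
#' residues reproduces the whole-protein original (for unit weighting, where
#' the original is defined):
#' \describe{
#'   \item{wCO}{`(1/(2 N N_c)) sum_j omega_ij delta_ij` (weighted contact
#'     order share).}
#'   \item{wLRO}{`(1/(2N)) sum_j omega_ij delta_ij` (long-range order share;
#'     sums to N_c/N).}
#'   \item{wTCD}{`(1/(2N^2)) sum_j |i-j| omega_ij delta_ij` (total contact
#'     distance share).}
#'   \item{wNc}{`sum_j omega_ij delta_ij` (weighted contact number; sums to
#'     2 N_c).}
#'   \item{wCLQ}{weighted clustering coefficient (cliquishness) of residue i
#'     on the contact graph: the omega-weighted fraction of contacting pairs
#'     among i's contact neighbours; 0 when the degree is below 2.}
#'   \item{lnFD}{log folding-degree contribution from backbone dihedral
#'     cosines (see [lnfd_index()]); does not use the contact map.}
#' }
#'
#' @param model the [ProteinModel][new_protein_model] the map was built from.
#' @param cm a [ContactMap][build_contact_map] (ignored for `lnFD`).
#' @param name one of `"wCO"`, `"wLRO"`, `"wTCD"`, `"wNc"`, `"wCLQ"`,
#'   `"lnFD"`.
#' @param zero_on_degenerate forwarded to [weighted_contact_order()].
#' @return An [IndexVector][new_index_vector].
#' @export
topographic_index <- function(model, cm, name,
                              zero_on_degenerate = FALSE) {
  if (!name %in% TOPOGRAPHIC_INDICES)
    stop("unknown topographic index '", name, "'; supported: ",
         paste(TOPOGRAPHIC_INDICES, collapse = ", "))
  if (name == "lnFD") return(lnfd_index(model))
  stopifnot(inherits(cm, "ContactMap"), cm$n == n_residues(model))
  if (name == "wCO")
    return(weighted_contact_order(cm, model$id, zero_on_degenerate))
  n <- cm$n
  wsum <- rowSums(cm$omega * cm$delta)
  vals <- switch(name,
    wNc  = wsum,
    wLRO = wsum / (2 * n),
    wTCD = {
      sep <- abs(outer(seq_len(n), seq_len(n), `-`))
      rowSums(sep * cm$omega * cm$delta) / (2 * n^2)
    },
    wCLQ = .cliquishness(cm)
  )
  new_index_vector(model$id, name, vals,
                   list(d = cm$d_cut, t = cm$t_cut, scheme = cm$scheme))
}

.cliquishness <- function(cm) {
  n <- cm$n
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(cm$delta[i, ])
    deg <- length(nb)
    if (deg < 2L) next
    sub_delta <- cm$delta[nb, nb, drop = FALSE]
    sub_omega <- cm$omega[nb, nb, drop = FALSE]
    vals[i] <- sum(sub_omega[sub_delta]) / 2 / choose(deg, 2)
  }
  vals
}

# -- folding degree -----------------------------------------------------------

# dihedral angle (radians) defined by four points (rows of a matrix)
.dihedral <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] / sqrt(sum(b2^2)) - n1[3] * b2[2] / sqrt(sum(b2^2)),
          n1[3] * b2[1] / sqrt(sum(b2^2)) - n1[1] * b2[3] / sqrt(sum(b2^2)),
          n1[1] * b2[2] / sqrt(sum(b2^2)) - n1[2] * b2[1] / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Backbone dihedral angles of a model
#'
#' Returns phi/psi (radians) from N/CA/C backbone atoms when available; for
#' CA-only models, both columns carry the CA pseudo-dihedral of the window
#' centred on the residue.  NA at chain ends.
#'
#' @inheritParams n_residues
#' @return N x 2 matrix with columns `phi`, `psi`.
#' @export
backbone_dihedrals <- function(model) {
  stop_if_no_structure(model, "backbone_dihedrals")
  n <- n_residues(model)
  at <- model$atoms
  getat <- function(i, nm) {
    r <- at[at$position == i & at$atom == nm, c("x", "y", "z")]
    if (nrow(r)) as.numeric(r[1, ]) else NULL
  }
  phi <- psi <- rep(NA_real_, n)
  full_bb <- all(c("N", "C") %in% at$atom)
  if (full_bb) {
    for (i in seq_len(n)) {
      Ni <- getat(i, "N"); CAi <- getat(i, "CA"); Ci <- getat(i, "C")
      if (i > 1) {
        Cp <- getat(i - 1, "C")
        if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci))
          phi[i] <- .dihedral(rbind(Cp, Ni, CAi, Ci))
      }
      if (i < n) {
        Nn <- getat(i + 1, "N")
        if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn))
          psi[i] <- .dihedral(rbind(Ni, CAi, Ci, Nn))
      }
    }
  } else {
    ca <- ca_coords(model)
    for (i in seq_len(n)) {
      if (i >= 2 && i <= n - 2 && !anyNA(ca[(i - 1):(i + 2), ])) {
        d <- .dihedral(ca[(i - 1):(i + 2), ])
        phi[i] <- d; psi[i] <- d
      }
    }
  }
  cbind(phi = phi, psi = psi)
}

#' Log folding-degree contribution per residue
#'
#' Each residue contributes `c_i = (2 + cos(phi_i) + cos(psi_i)) / (4 N)`
#' (missing dihedrals at chain ends contribute cosine 0), an Estrada-style
#' folding-degree share in (0, 1/N]; the index is `log(max(c_i, eps))`.
#'
#' @inheritParams n_residues
#' @param eps floor applied before the logarithm.
#' @return An [IndexVector][new_index_vector] named `lnFD`.
#' @export
lnfd_index <- function(model, eps = 1e-8) {
  dih <- backbone_dihedrals(model)
  n <- n_residues(model)
  cphi <- ifelse(is.na(dih[, "phi"]), 0, cos(dih[, "phi"]))
  cpsi <- ifelse(is.na(dih[, "psi"]), 0, cos(dih[, "psi"]))
  contrib <- (2 + cphi + cpsi) / (4 * n)
  new_index_vector(model$id, "lnFD", log(pmax(contrib, eps)),
                   list(eps = eps))
}
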