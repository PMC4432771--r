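# Solvent-accessible surface area via the Shrake-Rupley rolling-probe
# algorithm.  Sphere points come from a deterministic golden-section spiral,
# so results are bit-reproducible across runs.

#' Golden-section spiral points on the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(elements) {
  r <- VDW_RADII[elements]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

#' Compute per-residue solvent accessibility
#'
#' Runs Shrake-Rupley numerical SASA over all atoms of a structure-bearing
#' model and fills the `rel_sasa` residue column: the residue's absolute
#' accessible area divided by the theoretical maximum for its type (Tien et
#' al. style), clipped to \[0,1\].
#'
#' @param model a [ProteinModel][new_protein_model] with structure.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points number of test points per atom sphere.
#' @return The model with `rel_sasa` filled; the absolute per-residue areas
#'   (A^2) are attached as attribute `"abs_sasa"` on the residue table.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960L) {
  stop_if_no_structure(model, "compute_sasa")
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .atom_radii(at$element) + probe_radius
  n_at <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n_at)
  # neighbour lists from a single distance matrix; structures handled here
  # are protein-sized, so the O(n^2) matrix is cheap
  dm <- as.matrix(stats::dist(xyz))
  for (a in seq_len(n_at)) {
    nb <- which(dm[a, ] < rad[a] + rad & seq_len(n_at) != a)
    test <- sweep(pts * rad[a], 2, xyz[a, ], `+`)
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      d2 <- (test[, 1] - xyz[b, 1])^2 + (test[, 2] - xyz[b, 2])^2 +
        (test[, 3] - xyz[b, 3])^2
      acc <- acc & d2 >= rad[b]^2
      if (!any(acc)) break
    }
    area[a] <- 4 * pi * rad[a]^2 * sum(acc) / n_points
  }
  res_area <- vapply(seq_len(n_residues(model)), function(i)
    sum(area[at$position == i]), numeric(1))
  ref <- MAX_ASA[.aa_one(model$residues$aa)]
  model$residues$rel_sasa <- pmin(1, pmax(0, res_area / ref))
  attr(model$residues, "abs_sasa") <- res_area
  model
}
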