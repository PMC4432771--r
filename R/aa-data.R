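# Amino-acid constant tables used across the package.
#
# Property scales are taken from the original publications:
#   HP        Kyte & Doolittle (1982) hydropathy
#   z1,z2,z3  Hellberg et al. (1987) principal properties
#             (z1 hydrophilicity, z2 steric bulk, z3 polarity)
#   Pa,Pb,Pt  Levitt (1978) helix / sheet / turn conformational preferences
#   IP        isoelectric point of the free amino acid
#   Mw        average residue mass (Da)
# Reference maximal accessible surface areas are the Tien et al. (2013)
# theoretical maxima (A^2), used to express residue SASA as a fraction.

#' Standard amino-acid alphabet
#'
#' Twenty standard residues as three-letter codes, named by one-letter code.
#' @keywords internal
AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

#' @rdname AA3
#' @keywords internal
AA1 <- structure(names(AA3), names = AA3)

# Residues mapped onto a standard type before modelling; anything else is
# dropped with a warning.
NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", PYL = "LYS")

.aa_row <- function(...) {
  x <- c(...)
  stopifnot(length(x) == 20L)
  names(x) <- names(AA3)
  x
}

#' Built-in per-residue property scales
#'
#' A numeric matrix (20 residues x 9 scales) holding the bundled amino-acid
#' property scales.  Rows are named by one-letter code, columns by scale name
#' (`HP`, `z1`, `z2`, `z3`, `Pa`, `Pb`, `Pt`, `IP`, `Mw`).  Additional scales
#' (for example user-supplied electron-density-derived sets) can be added at
#' run time with [register_property_scales()].
#'
#' @seealso [property_index()], [register_property_scales()]
#' @export
BUILTIN_SCALES <- local({
  hp <- .aa_row(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
  z1 <- .aa_row(
    A =  0.07, R =  2.88, N =  3.22, D =  3.64, C =  0.71,
    Q =  2.18, E =  3.08, G =  2.23, H =  2.41, I = -4.44,
    L = -4.19, K =  2.84, M = -2.49, F = -4.92, P = -1.22,
    S =  1.96, T =  0.92, W = -4.75, Y = -1.39, V = -2.69
  )
  z2 <- .aa_row(
    A = -1.73, R =  2.52, N =  1.45, D =  1.13, C = -0.97,
    Q =  0.53, E =  0.39, G = -5.36, H =  1.74, I = -1.68,
    L = -1.03, K =  1.41, M = -0.27, F =  1.30, P =  0.88,
    S = -1.63, T = -2.09, W =  3.65, Y =  2.32, V = -2.53
  )
  z3 <- .aa_row(
    A =  0.09, R = -3.44, N =  0.84, D =  2.36, C =  4.13,
    Q = -1.14, E = -0.07, G =  0.30, H =  1.11, I = -1.03,
    L = -0.98, K = -3.14, M = -0.41, F =  0.45, P =  2.23,
    S =  0.57, T = -1.40, W =  0.85, Y =  0.01, V = -1.29
  )
  pa <- .aa_row(
    A = 1.29, R = 0.96, N = 0.90, D = 1.04, C = 1.11,
    Q = 1.27, E = 1.44, G = 0.56, H = 1.22, I = 0.97,
    L = 1.30, K = 1.23, M = 1.47, F = 1.07, P = 0.52,
    S = 0.82, T = 0.82, W = 0.99, Y = 0.72, V = 0.91
  )
  pb <- .aa_row(
    A = 0.90, R = 0.99, N = 0.76, D = 0.72, C = 0.74,
    Q = 0.80, E = 0.75, G = 0.92, H = 1.08, I = 1.45,
    L = 1.02, K = 0.77, M = 0.97, F = 1.32, P = 0.64,
    S = 0.95, T = 1.21, W = 1.14, Y = 1.25, V = 1.49
  )
  pt <- .aa_row(
    A = 0.78, R = 0.88, N = 1.28, D = 1.41, C = 0.80,
    Q = 0.97, E = 1.00, G = 1.64, H = 0.69, I = 0.51,
    L = 0.59, K = 0.96, M = 0.39, F = 0.58, P = 1.91,
    S = 1.33, T = 1.03, W = 0.75, Y = 1.05, V = 0.47
  )
  ip <- .aa_row(
    A =  6.00, R = 10.76, N =  5.41, D =  2.77, C =  5.07,
    Q =  5.65, E =  3.22, G =  5.97, H =  7.59, I =  6.02,
    L =  5.98, K =  9.74, M =  5.74, F =  5.48, P =  6.30,
    S =  5.68, T =  5.60, W =  5.89, Y =  5.66, V =  5.96
  )
  mw <- .aa_row(
    A =  71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
    Q = 128.13, E = 129.12, G =  57.05, H = 137.14, I = 113.16,
    L = 113.16, K = 128.17, M = 131.19, F = 147.18, P =  97.12,
    S =  87.08, T = 101.10, W = 186.21, Y = 163.18, V =  99.13
  )
  cbind(HP = hp, z1 = z1, z2 = z2, z3 = z3,
        Pa = pa, Pb = pb, Pt = pt, IP = ip, Mw = mw)
})

# Tien et al. (2013) theoretical maximal ASA per residue type (A^2).
MAX_ASA <- .aa_row(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  Q = 225, E = 223, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174
)

# Formal side-chain charge at neutral pH (His treated as half-protonated).
AA_CHARGE <- .aa_row(
  A = 0, R = 1, N = 0, D = -1, C = 0,
  Q = 0, E = -1, G = 0, H = 0.5, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0,
  S = 0, T = 0, W = 0, Y = 0, V = 0
)

# Van der Waals radii by element (A), Bondi values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Physicochemical class membership (one-letter codes).  HIS deliberately sits
# in both the basic and aromatic classes.
PROPERTY_CLASSES <- list(
  polar     = c("S", "T", "N", "Q", "Y", "C", "D", "E", "K", "R", "H", "W"),
  nonpolar  = c("A", "V", "L", "I", "M", "F", "P", "G"),
  basic     = c("K", "R", "H"),
  acidic    = c("D", "E"),
  aromatic  = c("F", "W", "Y", "H"),
  aliphatic = c("A", "V", "L", "I"),
  charged   = c("D", "E", "K", "R", "H"),
  tiny      = c("A", "G", "S", "C"),
  small     = c("A", "G", "S", "C", "T", "P", "N", "D", "V")
)

.aa_one <- function(aa3) {
  out <- AA1[aa3]
  unname(out)
}

.aa_three <- function(aa1) {
  unname(AA3[aa1])
}
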