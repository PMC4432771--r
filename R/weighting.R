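# Neighbourhood weighting operators: classical cheminformatics transforms
# applied on sequence topology (topological distance d_ij = |j - i|) to a
# per-residue index vector before grouping and aggregation.  Boundaries are
# truncated: a residue without a neighbour at the required distance simply
# sums fewer (possibly zero) terms.

WEIGHT_OPERATORS <- c("NONE", "AC", "KH", "ES", "IB", "GR")

#' Weighting operator specification
#'
#' @param operator one of `"NONE"`, `"AC"` (autocorrelation), `"KH"`
#'   (Kier-Hall-like), `"ES"` (electrotopological-state-like), `"IB"`
#'   (Ivanciuc-Balaban-like), `"GR"` (gravitational-like).
#' @param k topological distance cut-off; required (>= 1) for AC, KH and GR,
#'   ignored for NONE, ES and IB.
#' @return An object of class `WeightingSpec`.
#' @export
weighting_spec <- function(operator = "NONE", k = NULL) {
  operator <- toupper(operator)
  if (!operator %in% WEIGHT_OPERATORS)
    stop("unknown weighting operator '", operator, "'; supported: ",
         paste(WEIGHT_OPERATORS, collapse = ", "))
  if (operator %in% c("AC", "KH", "GR")) {
    if (is.null(k) || k < 1)
      stop("operator ", operator, " requires a topological cut-off k >= 1")
    k <- as.integer(k)
  } else k <- NA_integer_
  structure(list(operator = operator, k = k), class = "WeightingSpec")
}

#' Tag used in descriptor names for a weighting spec
#' @param spec a [weighting_spec()].
#' @return `""` for NONE, otherwise e.g. `"AC2"`, `"ES"`.
#' @export
weighting_tag <- function(spec) {
  if (spec$operator == "NONE") ""
  else if (is.na(spec$k)) spec$operator
  else paste0(spec$operator, spec$k)
}

#' Parse a weighting tag
#'
#' Inverse of [weighting_tag()]: `"NONE"`, `"AC2"`, `"ES"`, ... to a spec.
#' @param tag character tag.
#' @return A [weighting_spec()].
#' @export
parse_weighting <- function(tag) {
  tag <- toupper(trimws(tag))
  op <- sub("[0-9]+$", "", tag)
  k <- sub("^[A-Z]+", "", tag)
  weighting_spec(op, if (nzchar(k)) as.integer(k) else NULL)
}

#' Autocorrelation weighting
#'
#' `AC_i = sum_j L_i L_j` over the residues j at topological distance
#' exactly k from i (`|j - i| = k`): two products for interior residues, one
#' near the termini, zero (with a warning) when `k >= N`.
#'
#' @param L numeric vector or [IndexVector][new_index_vector].
#' @param k topological distance cut-off, `1 <= k`.
#' @return Same shape as the input (IndexVector in, IndexVector out, with
#'   `_ACk` appended to the index name).
#' @export
autocorrelation <- function(L, k) {
  v <- .iv_values(L)
  n <- length(v)
  k <- as.integer(k)
  if (k < 1) stop("autocorrelation requires k >= 1")
  out <- numeric(n)
  if (k >= n) {
    warning("k >= protein length: no residue pair at distance ", k,
            "; returning zeros")
  } else {
    idx <- seq_len(n - k)
    out[idx] <- out[idx] + v[idx] * v[idx + k]
    out[idx + k] <- out[idx + k] + v[idx + k] * v[idx]
  }
  .iv_like(L, out, suffix = paste0("AC", k), params = list(k = k))
}

#' Apply a weighting operator to an index vector
#'
#' Closed forms (topological distance `d_ij = |j - i|`, truncated
#' boundaries, `eps` guards inverse-square-root terms):
#' \describe{
#'   \item{NONE}{identity.}
#'   \item{AC}{[autocorrelation()].}
#'   \item{ES}{`L_i' = L_i + sum_{j != i} (L_i - L_j) / (d_ij + 1)^2`.}
#'   \item{GR}{`L_i' = sum_{j != i, d_ij <= k} L_i L_j / d_ij^2`.}
#'   \item{KH}{`L_i' = sum_{d_ij = k} sign(L_i L_j) |L_i L_j|^(-1/2)`,
#'     dropping terms with `|L_i L_j| < eps`.}
#'   \item{IB}{`L_i' = sum_{d_ij = 1} sign(S_i S_j) |S_i S_j|^(-1/2)` with
#'     distance sums `S_i = sum_j d_ij L_j`, same eps rule.}
#' }
#' Degenerate terms are dropped, never raised.
#'
#' @param L numeric vector or [IndexVector][new_index_vector].
#' @param spec a [weighting_spec()] (or a tag accepted by
#'   [parse_weighting()]).
#' @param eps drop threshold for inverse-square-root terms.
#' @return Transformed vector, same shape as the input.
#' @export
apply_weighting <- function(L, spec, eps = 1e-12) {
  if (is.character(spec)) spec <- parse_weighting(spec)
  stopifnot(inherits(spec, "WeightingSpec"))
  v <- .iv_values(L)
  n <- length(v)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  out <- switch(spec$operator,
    NONE = v,
    AC = return(autocorrelation(L, spec$k)),
    ES = {
      diff <- outer(v, v, `-`)            # diff[i,j] = L_i - L_j; 0 at i=j
      v + rowSums(diff / (d + 1)^2)
    },
    GR = {
      w <- matrix(0, n, n)
      sel <- d >= 1 & d <= spec$k
      w[sel] <- 1 / d[sel]^2
      v * as.numeric(w %*% v)
    },
    KH = {
      out_i <- numeric(n)
      sel <- d == spec$k
      if (any(sel)) {
        prod_ij <- outer(v, v)
        term <- matrix(0, n, n)
        ok <- sel & abs(prod_ij) >= eps
        term[ok] <- sign(prod_ij[ok]) / sqrt(abs(prod_ij[ok]))
        out_i <- rowSums(term)
      }
      out_i
    },
    IB = {
      S <- as.numeric(d %*% v)
      prod_ij <- outer(S, S)
      term <- matrix(0, n, n)
      ok <- d == 1 & abs(prod_ij) >= eps
      term[ok] <- sign(prod_ij[ok]) / sqrt(abs(prod_ij[ok]))
      rowSums(term)
    }
  )
  .iv_like(L, out, suffix = {
    tag <- weighting_tag(spec)
    if (nzchar(tag)) tag else NULL
  }, params = list(k = spec$k))
}
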