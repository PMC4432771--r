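#' Construct an IndexVector
#'
#' An `IndexVector` holds one real value per residue for a named per-residue
#' index (the L vector that weighting operators transform and aggregation
#' collapses).
#'
#' @param protein_id protein identifier.
#' @param index_name index name (e.g. `"HP"`, `"wCO"`).
#' @param values numeric vector, one finite value per residue.
#' @param params named list of parameters the index was computed with.
#' @return An object of class `IndexVector`.
#' @export
new_index_vector <- function(protein_id, index_name, values,
                             params = list()) {
  values <- as.numeric(values)
  if (!length(values)) stop("IndexVector must be non-empty")
  if (any(!is.finite(values)))
    stop(sprintf("non-finite value in index '%s' of protein '%s'",
                 index_name, protein_id))
  structure(
    list(protein_id = protein_id, index_name = index_name,
         values = values, params = params),
    class = "IndexVector"
  )
}

#' @export
print.IndexVector <- function(x, ...) {
  cat(sprintf("IndexVector %s[%s]: N=%d, range [%.4g, %.4g]\n",
              x$protein_id, x$index_name, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# coerce numeric or IndexVector input to plain numeric
.iv_values <- function(L) if (inherits(L, "IndexVector")) L$values else
  as.numeric(L)

# rebuild an IndexVector around transformed values, preserving metadata
.iv_like <- function(L, values, suffix = NULL, params = list()) {
  if (inherits(L, "IndexVector"))
    new_index_vector(L$protein_id,
                     if (is.null(suffix)) L$index_name
                     else paste0(L$index_name, "_", suffix),
                     values, c(L$params, params))
  else values
}
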