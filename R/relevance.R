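# Descriptor relevance via histogram Shannon entropy, and inter-protein
# distance matrices over the descriptor table.

#' Rank descriptors by Shannon-entropy variability
#'
#' For each descriptor column the values across proteins are binned into
#' `n_bins` equal-width bins spanning \[min, max\] and the entropy
#' `H = -sum p_b log2 p_b` is computed.  Constant columns have H = 0;
#' columns that are entirely the missing sentinel are excluded with a
#' warning.  Descriptors with (almost) zero entropy are trivial: they do not
#' help to tell proteins apart and can be filtered before model building.
#'
#' @param table a [descriptor_table()] with at least two proteins.
#' @param n_bins number of histogram bins (>= 2; default 20).
#' @return A data frame with columns `descriptor` and `entropy` (bits),
#'   sorted by decreasing entropy, ties broken by descriptor name.
#' @export
shannon_relevance <- function(table, n_bins = 20L) {
  stopifnot(nrow(table) >= 2L, n_bins >= 2L)
  ent <- rep(NA_real_, ncol(table))
  for (j in seq_len(ncol(table))) {
    v <- table[, j]
    v <- v[!is.na(v)]
    if (!length(v)) next
    ent[j] <- .hist_entropy(v, n_bins)
  }
  drop <- is.na(ent)
  if (any(drop))
    warning(sprintf("excluded %d all-sentinel descriptor column(s)",
                    sum(drop)))
  out <- data.frame(descriptor = colnames(table)[!drop],
                    entropy = ent[!drop], stringsAsFactors = FALSE)
  out[order(-out$entropy, out$descriptor), , drop = FALSE]
}

.hist_entropy <- function(v, n_bins) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  # equal-width bins over [min, max]; right-closed, lowest bin closed
  b <- findInterval(v, seq(rng[1], rng[2], length.out = n_bins + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(b, nbins = n_bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Inter-protein distance matrix over descriptors
#'
#' Computes pairwise protein distances in descriptor space.  Columns
#' carrying any missing sentinel are excluded (with a message), so the
#' metric is evaluated over a common complete set of descriptors.
#'
#' @param table a [descriptor_table()] with at least two proteins.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A symmetric matrix with zero diagonal, dimnames = protein ids.
#' @export
distance_matrix <- function(table, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(nrow(table) >= 2L)
  usable <- colSums(is.na(table)) == 0L
  if (any(!usable))
    message(sprintf("distance_matrix: excluded %d column(s) with sentinels",
                    sum(!usable)))
  if (sum(usable) < 2L)
    stop("fewer than 2 usable descriptor columns for distance computation")
  d <- stats::dist(unclass(table)[, usable, drop = FALSE], method = metric)
  m <- as.matrix(d)
  dimnames(m) <- list(rownames(table), rownames(table))
  m
}

#' Write a matrix or relevance ranking as TSV
#' @param x matrix or data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.matrix(x)) {
    lines <- c(paste(c("", colnames(x)), collapse = "\t"),
               vapply(seq_len(nrow(x)), function(r)
                 paste(c(rownames(x)[r], sprintf("%.6E", x[r, ])),
                       collapse = "\t"), ""))
    writeLines(lines, path)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
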