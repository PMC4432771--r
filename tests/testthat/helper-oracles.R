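# Independent reference implementations used as oracles.  These are written
# as naive double loops directly from the defining formulas and share no
# code with the package internals they check.

# autocorrelation: sum over all j with |j - i| = k of L_i * L_j
oracle_autocorrelation <- function(v, k) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(j - i) == k) out[i] <- out[i] + v[i] * v[j]
  out
}

oracle_es <- function(v) {
  n <- length(v)
  out <- v
  for (i in seq_len(n)) for (j in seq_len(n)) if (j != i)
    out[i] <- out[i] + (v[i] - v[j]) / (abs(j - i) + 1)^2
  out
}

oracle_gr <- function(v, k) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- abs(j - i)
    if (j != i && d <= k) out[i] <- out[i] + v[i] * v[j] / d^2
  }
  out
}

oracle_kh <- function(v, k, eps = 1e-12) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (abs(j - i) == k) {
    p <- v[i] * v[j]
    if (abs(p) >= eps) out[i] <- out[i] + sign(p) / sqrt(abs(p))
  }
  out
}

oracle_ib <- function(v, eps = 1e-12) {
  n <- length(v)
  S <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i] <- S[i] + abs(j - i) * v[j]
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (abs(j - i) == 1) {
    p <- S[i] * S[j]
    if (abs(p) >= eps) out[i] <- out[i] + sign(p) / sqrt(abs(p))
  }
  out
}

# contact map by explicit double loop on CA coordinates
oracle_contacts <- function(xyz, d_cut, t_cut) {
  n <- nrow(xyz)
  delta <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    delta[i, j] <- r < d_cut && abs(i - j) > t_cut
  }
  delta
}

# whole-protein contact order straight from its original definition
oracle_contact_order <- function(xyz, d_cut = 8, t_cut = 4) {
  n <- nrow(xyz)
  s <- 0; nc <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < d_cut && (j - i) > t_cut) { s <- s + (j - i); nc <- nc + 1L }
  }
  if (nc == 0L) return(NULL)
  list(co = s / (n * nc), nc = nc)
}

oracle_lro <- function(xyz, d_cut = 8, t_cut = 4) {
  n <- nrow(xyz)
  nc <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < d_cut && (j - i) > t_cut) nc <- nc + 1L
  }
  nc / n
}

oracle_tcd <- function(xyz, d_cut = 8, t_cut = 4) {
  n <- nrow(xyz)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < d_cut && (j - i) > t_cut) s <- s + (j - i)
  }
  s / n^2
}

# histogram entropy from first principles
oracle_hist_entropy <- function(v, n_bins) {
  if (min(v) == max(v)) return(0)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  counts <- integer(n_bins)
  for (x in v) {
    b <- n_bins
    for (k in seq_len(n_bins - 1))
      if (x >= edges[k] && x < edges[k + 1]) { b <- k; break }
    counts[b] <- counts[b] + 1L
  }
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

# brute-force numerical SASA with a latitude-longitude point grid,
# independent of the package's golden-spiral implementation
oracle_sasa_atoms <- function(xyz, radii, probe = 1.4, n_lat = 40L) {
  n <- nrow(xyz)
  lat <- (seq_len(n_lat) - 0.5) / n_lat * pi
  pts <- NULL
  for (th in lat) {
    n_lon <- max(1L, round(2 * n_lat * sin(th)))
    lon <- (seq_len(n_lon) - 0.5) / n_lon * 2 * pi
    pts <- rbind(pts, cbind(sin(th) * cos(lon), sin(th) * sin(lon),
                            rep(cos(th), n_lon)))
  }
  area <- numeric(n)
  for (a in seq_len(n)) {
    r <- radii[a] + probe
    acc <- 0L
    for (p in seq_len(nrow(pts))) {
      tp <- xyz[a, ] + r * pts[p, ]
      free <- TRUE
      for (b in seq_len(n)) {
        if (b == a) next
        if (sum((tp - xyz[b, ])^2) < (radii[b] + probe)^2) {
          free <- FALSE; break
        }
      }
      if (free) acc <- acc + 1L
    }
    area[a] <- 4 * pi * r^2 * acc / nrow(pts)
  }
  area
}

# random sequence helper
random_sequence <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

write_fasta_tmp <- function(records) {
  f <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (nm in names(records))
    lines <- c(lines, paste0(">", nm), records[[nm]])
  writeLines(lines, f)
  f
}
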