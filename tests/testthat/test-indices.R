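# Contact maps, topographic indices, property scales, thermodynamic terms.

test_that("contact conditions require distance < d AND separation > t", {
  # two residues 10 apart in sequence, CA 5 A apart: contact
  res <- data.frame(position = 1:11, aa = "ALA", resseq = 1:11,
                    ss = "COIL", rel_sasa = NA_real_)
  atoms <- data.frame(position = 1:11, atom = "CA",
                      x = c(0, 100, 200, 300, 400, 500, 600, 700, 800,
                            900, 5),
                      y = 0, z = 0, element = "C")
  m <- new_protein_model("far", res, atoms)
  cm <- build_contact_map(m, d_cut = 8, t_cut = 4)
  expect_true(cm$delta[1, 11])

  # |i-j| = 4 at 3 A is NOT a contact (4 is not > 4)
  res4 <- data.frame(position = 1:5, aa = "GLY", resseq = 1:5,
                     ss = "COIL", rel_sasa = NA_real_)
  at4 <- data.frame(position = 1:5, atom = "CA",
                    x = c(0, 50, 100, 150, 3), y = 0, z = 0,
                    element = "C")
  m4 <- new_protein_model("sep4", res4, at4)
  cm4 <- build_contact_map(m4, d_cut = 8, t_cut = 4)
  expect_false(cm4$delta[1, 5])
  expect_equal(cm4$n_contacts, 0L)
})

test_that("contact map matches the brute-force double loop on random coils", {
  for (seed in 1:5) {
    m <- synthetic_structure("coil", 30, seed = seed)
    cm <- build_contact_map(m, d_cut = 8, t_cut = 4)
    ref <- oracle_contacts(ca_coords(m), 8, 4)
    expect_identical(unname(cm$delta), ref)
    expect_identical(cm$n_contacts, sum(ref) / 2)
    expect_identical(cm$delta, t(cm$delta))
    expect_false(any(diag(cm$delta)))
  }
})

test_that("omega follows the weighting scheme", {
  m <- synthetic_structure("coil", 12, seed = 2)
  sep <- abs(outer(1:12, 1:12, `-`))
  expect_equal(build_contact_map(m, weight_scheme = "none")$omega,
               matrix(1, 12, 12))
  expect_equal(build_contact_map(m, weight_scheme = "seq_separation")$omega,
               sep * 1.0)
  w <- property_index(m, "HP")$values
  expect_equal(build_contact_map(m, weight_scheme = "property:HP")$omega,
               outer(w, w))
  expect_error(build_contact_map(m, weight_scheme = "nonsense"),
               "weight scheme")
})

test_that("wCO residue values sum to 1/N under unit weighting", {
  for (seed in 1:4) {
    m <- synthetic_structure("cluster", 25, seed = seed)
    cm <- build_contact_map(m, weight_scheme = "none")
    wco <- weighted_contact_order(cm, m$id)
    expect_equal(sum(wco$values), 1 / n_residues(m), tolerance = 1e-12)
  }
})

test_that("sequence-separation wCO reproduces the whole-protein contact order", {
  m <- synthetic_structure("coil", 40, seed = 8)
  cm <- build_contact_map(m, weight_scheme = "seq_separation")
  ref <- oracle_contact_order(ca_coords(m))
  expect_false(is.null(ref))
  expect_equal(sum(weighted_contact_order(cm)$values), ref$co,
               tolerance = 1e-12)
})

test_that("property-weighted wCO matches an independent pair loop", {
  m <- synthetic_structure("coil", 40, seed = 13)
  cm <- build_contact_map(m, weight_scheme = "property:HP")
  wco <- weighted_contact_order(cm, m$id)
  hp <- property_index(m, "HP")$values
  delta <- oracle_contacts(ca_coords(m), 8, 4)
  nc <- sum(delta) / 2
  n <- 40
  ref <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j != i && delta[i, j])
      ref[i] <- ref[i] + hp[i] * hp[j] / (2 * n * nc)
  expect_equal(wco$values, ref, tolerance = 1e-12)
})

test_that("degenerate contact maps error unless zeros are requested", {
  m <- synthetic_structure("helix", 10, seed = 1)  # straight ideal helix:
  cm <- build_contact_map(m)                       # no |i-j|>4 pair < 8 A
  expect_equal(cm$n_contacts, 0L)
  expect_error(weighted_contact_order(cm), "no contacts")
  expect_equal(weighted_contact_order(cm, zero_on_degenerate = TRUE)$values,
               numeric(10))
  expect_equal(topographic_index(m, cm, "wNc")$values, numeric(10))
  expect_equal(topographic_index(m, cm, "wCLQ")$values, numeric(10))
})

test_that("residue sums of wLRO/wTCD/wNc recover the original formulas", {
  for (seed in c(5, 6)) {
    m <- synthetic_structure("coil", 50, seed = seed)
    cm <- build_contact_map(m, weight_scheme = "none")
    xyz <- ca_coords(m)
    expect_equal(sum(topographic_index(m, cm, "wLRO")$values),
                 oracle_lro(xyz), tolerance = 1e-12)
    expect_equal(sum(topographic_index(m, cm, "wNc")$values),
                 2 * (sum(oracle_contacts(xyz, 8, 4)) / 2),
                 tolerance = 1e-12)
    expect_equal(sum(topographic_index(m, cm, "wTCD")$values),
                 oracle_tcd(xyz), tolerance = 1e-12)
  }
})

test_that("cliquishness is 1 on a triangle and 0 for low-degree residues", {
  res <- data.frame(position = 1:13, aa = "ALA", resseq = 1:13,
                    ss = "COIL", rel_sasa = NA_real_)
  # residues 1, 7, 13 form a mutually contacting triangle (sep > 4);
  # everything else is far away
  xs <- c(0, 1000, 2000, 3000, 4000, 5000, 4, 6000, 7000, 8000, 9000,
          10000, 2)
  ys <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3.5)
  atoms <- data.frame(position = 1:13, atom = "CA", x = xs, y = ys,
                      z = 0, element = "C")
  m <- new_protein_model("tri", res, atoms)
  cm <- build_contact_map(m, d_cut = 8, t_cut = 4)
  expect_true(all(cm$delta[1, 7], cm$delta[7, 13], cm$delta[1, 13]))
  clq <- topographic_index(m, cm, "wCLQ")$values
  expect_equal(clq[c(1, 7, 13)], c(1, 1, 1))
  expect_equal(clq[2:6], numeric(5))
  expect_error(topographic_index(m, cm, "bogus"), "supported")
})

test_that("index vectors are invariant under rigid-body motion", {
  m <- synthetic_structure("coil", 25, seed = 21)
  # random rotation (QR of a fixed matrix) + translation
  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% Q
  m2$atoms$x <- xyz[, 1] + 13.7
  m2$atoms$y <- xyz[, 2] - 4.2
  m2$atoms$z <- xyz[, 3] + 0.5
  for (nm in c("wCO", "wLRO", "wNc", "wCLQ", "lnFD")) {
    cm1 <- build_contact_map(m, weight_scheme = "seq_separation")
    cm2 <- build_contact_map(m2, weight_scheme = "seq_separation")
    v1 <- topographic_index(m, cm1, nm)$values
    v2 <- topographic_index(m2, cm2, nm)$values
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})

test_that("property indices are pure lookups", {
  f <- write_fasta_tmp(list(s = "IIIRRR"))
  m <- read_fasta(f)[[1]]
  hp <- property_index(m, "HP")$values
  expect_true(all(hp[1:3] > hp[4:6]))  # ILE hydrophobic, ARG not
  expect_equal(hp[1:3], rep(4.5, 3))

  clear_property_scales()
  register_property_scales(matrix(
    1, 20, 1, dimnames = list(rownames(protdescr::BUILTIN_SCALES),
                              "ONES")))
  expect_equal(property_index(m, "ONES")$values, rep(1, 6))
  clear_property_scales()
  expect_error(property_index(m, "ONES"), "registered scales")
})

test_that("a many-column user property table registers all its scales", {
  tab <- matrix(seq_len(20 * 147), 20, 147,
                dimnames = list(rownames(protdescr::BUILTIN_SCALES),
                                paste0("T", 1:147)))
  register_property_scales(tab)
  expect_true(all(paste0("T", 1:147) %in% list_property_scales()))
  f <- write_fasta_tmp(list(s = "AA"))
  m <- read_fasta(f)[[1]]
  expect_equal(property_index(m, "T5")$values, rep(tab["A", "T5"], 2))
  clear_property_scales()
})

test_that("property tables load from tab-delimited files", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("AA\tS1\tS2",
               paste(rownames(protdescr::BUILTIN_SCALES),
                     1:20, 21:40, sep = "\t")), path)
  load_property_table(path)
  expect_true(all(c("S1", "S2") %in% list_property_scales()))
  clear_property_scales()
})

test_that("thermodynamic index boundary behaviour", {
  # no charged residues -> electrostatic term identically zero
  m0 <- synthetic_structure("coil", 10, seed = 4,
                            sequence = "AAGGLLVVII")
  expect_equal(thermodynamic_index(m0, "Ele")$values, numeric(10))

  # two opposite charges moved apart: per-residue magnitude decreases
  mk <- function(dist) {
    res <- data.frame(position = 1:2, aa = c("LYS", "ASP"), resseq = 1:2,
                      ss = "COIL", rel_sasa = NA_real_)
    at <- data.frame(position = 1:2, atom = "CA", x = c(0, dist), y = 0,
                     z = 0, element = "C")
    new_protein_model("pair", res, at)
  }
  e5 <- thermodynamic_index(mk(5), "Ele")$values
  e10 <- thermodynamic_index(mk(10), "Ele")$values
  expect_true(all(abs(e10) < abs(e5)))
  expect_true(all(e5 < 0))  # opposite charges: favourable, negative

  # hydrophobic term: fully exposed -> 0, fully buried -> scale value
  mh <- synthetic_structure("coil", 5, seed = 5, sequence = "ILIVF")
  mh$residues$rel_sasa <- c(1, 0, 1, 0, 0.5)
  hph <- thermodynamic_index(mh, "Hph")$values
  hp <- property_index(mh, "HP")$values
  expect_equal(hph[c(1, 3)], c(0, 0))
  expect_equal(hph[c(2, 4)], hp[c(2, 4)])

  # structure-based members refuse sequence-only input
  f <- write_fasta_tmp(list(s = "MKTAYIAK"))
  mseq <- read_fasta(f)[[1]]
  expect_error(thermodynamic_index(mseq, "Vdw"), "sequence-only")
  expect_equal(thermodynamic_index(mseq, "HphS")$values,
               property_index(mseq, "HP")$values)
  expect_error(thermodynamic_index(mseq, "nope"), "supported")
})
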