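# The combinatorial engine: naming, column counts, outputs, relevance,
# distances, project configs.

make_fasta_models <- function() {
  f <- write_fasta_tmp(list(p1 = "HGGGWGQP", p2 = "ACDEFGHIKLMNPQRSTVWY",
                            p3 = "AAAAKKKKDDDD"))
  read_fasta(f)
}

test_that("minimal configuration gives a proteins x 1 table", {
  models <- make_fasta_models()
  cfg <- project_config(indices = "HP", weightings = "NONE",
                        groups = "PRT", aggregators = "Q2")
  res <- generate_descriptors(models, cfg)
  expect_equal(dim(res$table), c(3L, 1L))
  expect_equal(colnames(res$table), "HP_PRT_Q2")
})

test_that("HP_PRT_Q2 equals the hand-computed median of the scale values", {
  models <- make_fasta_models()
  cfg <- project_config(indices = "HP", weightings = "NONE",
                        groups = "PRT", aggregators = "Q2")
  res <- generate_descriptors(models, cfg)
  # Kyte-Doolittle values of H,G,G,G,W,G,Q,P by hand
  hand <- stats::median(c(-3.2, -0.4, -0.4, -0.4, -0.9, -0.4, -3.5, -1.6))
  expect_equal(unname(res$table["p1", "HP_PRT_Q2"]), hand)
})

test_that("column count law |I| x |W| x |G| x |A| with unique names", {
  models <- make_fasta_models()
  cfg <- project_config(
    indices = c("HP", "z2"), weightings = c("NONE", "AC2", "ES"),
    groups = c("PRT", "GLY", "polar", "acidic"),
    aggregators = c("AM", "Q2", "N1", "SD", "MIC"))
  res <- generate_descriptors(models, cfg)
  expect_equal(ncol(res$table), 2L * 3L * 4L * 5L)
  expect_false(anyDuplicated(colnames(res$table)) > 0)
  expect_true("HP_AC2_polar_SD" %in% colnames(res$table))
  expect_true("z2_ES_acidic_MIC" %in% colnames(res$table))
})

test_that("residue tables carry labelled rows and weighted index columns", {
  models <- make_fasta_models()
  cfg <- project_config(indices = c("HP"), weightings = c("NONE", "AC2"),
                        groups = "PRT", aggregators = "AM")
  res <- generate_descriptors(models, cfg)
  rt <- res$residue_tables[[1]]
  expect_equal(rownames(rt)[1], "p1_aa1_HIS")
  expect_equal(rownames(rt)[8], "p1_aa8_PRO")
  expect_equal(colnames(rt), c("HP", "HP_AC2"))
  expect_equal(rt[, "HP_AC2"],
               stats::setNames(autocorrelation(rt[, "HP"], 2),
                               rownames(rt)))
})

test_that("structure-only selections on FASTA input sentinel-fill or error", {
  models <- make_fasta_models()
  cfg <- project_config(indices = c("HP", "wCO"), weightings = "NONE",
                        groups = c("PRT", "INT"), aggregators = "AM")
  expect_message(res <- generate_descriptors(models, cfg), "sentinel")
  expect_equal(ncol(res$table), 4L)                 # columns kept
  expect_true(all(is.na(res$table[, "wCO_PRT_AM"])))
  expect_true(all(is.na(res$table[, "HP_INT_AM"])))
  expect_false(anyNA(res$table[, "HP_PRT_AM"]))
  cfg$strict <- TRUE
  expect_error(generate_descriptors(models, cfg), "strict")
})

test_that("empty groups produce sentinel cells but keep the column", {
  models <- make_fasta_models()                     # p3 has no GLY
  cfg <- project_config(indices = "HP", weightings = "NONE",
                        groups = "GLY", aggregators = "AM")
  suppressMessages(res <- generate_descriptors(models, cfg))
  expect_true(is.na(res$table["p3", "HP_GLY_AM"]))
  expect_false(is.na(res$table["p1", "HP_GLY_AM"]))
})

test_that("outputs write, round-trip and keep sentinels", {
  models <- make_fasta_models()
  cfg <- project_config(indices = "HP", weightings = c("NONE", "AC2"),
                        groups = c("PRT", "GLY"),
                        aggregators = c("AM", "Q2"))
  suppressMessages(res <- generate_descriptors(models, cfg))
  prefix <- file.path(tempdir(), "engio", "run")
  paths <- write_outputs(res$residue_tables, res$table, prefix)
  aa_lines <- readLines(paths[1])
  expect_match(aa_lines[2], "^p1_aa1_HIS\t")
  back <- read_descriptor_table(paths[2])
  expect_equal(unclass(back), unclass(res$table), tolerance = 1e-6)
  expect_identical(is.na(back), is.na(res$table))
})

test_that("full structure pipeline runs on synthetic PDB input", {
  dirp <- file.path(tempdir(), "structrun")
  dir.create(dirp, showWarnings = FALSE)
  p1 <- write_model_pdb(synthetic_structure("cluster", 25, seed = 1),
                        file.path(dirp, "c1.pdb"))
  p2 <- write_model_pdb(synthetic_structure("coil", 25, seed = 2),
                        file.path(dirp, "c2.pdb"))
  cfg <- project_config(
    inputs = c(p1, p2),
    indices = c("wCO", "wNc", "lnFD", "Hph", "HP"),
    weightings = c("NONE", "GR2"),
    groups = c("PRT", "INT", "SUP", "RCL"),
    aggregators = c("AM", "N2", "SK"),
    contact_weight = "seq_separation",
    zero_on_degenerate = TRUE,
    output_prefix = file.path(dirp, "out"))
  r <- run_project(cfg)
  expect_true(all(file.exists(r)))
  tab <- read_descriptor_table(r[["prot"]])
  expect_equal(dim(tab), c(2L, 5L * 2L * 4L * 3L))
  expect_false(anyNA(tab[, "wCO_PRT_AM"]))
})

test_that("saved configs reload losslessly and re-runs are byte-identical", {
  models_file <- write_fasta_tmp(list(a = "HGGGWGQP", b = "MKTAYIAKQRQISFVK"))
  prefix <- file.path(tempdir(), "repro", "run")
  cfg <- project_config(
    inputs = models_file, indices = c("HP", "z1"),
    weightings = c("NONE", "AC2", "IB"), groups = c("PRT", "polar"),
    aggregators = c("AM", "Q2", "TIC"), output_prefix = prefix)
  cfg_path <- file.path(tempdir(), "repro", "cfg.yaml")
  write_project_config(cfg, cfg_path)
  cfg2 <- read_project_config(cfg_path)
  expect_equal(unclass(cfg2)[order(names(cfg2))],
               unclass(cfg)[order(names(cfg))])
  r1 <- run_project(cfg_path)
  bytes1 <- lapply(r1[c("aa", "prot")], readLines)
  r2 <- run_project(cfg_path)
  bytes2 <- lapply(r2[c("aa", "prot")], readLines)
  expect_identical(bytes1, bytes2)
})

test_that("config validation names the offending field", {
  expect_error(project_config(indices = "NOPE"), "indices")
  expect_error(project_config(groups = "NOPE"), "groups")
  expect_error(project_config(aggregators = "NOPE"), "aggregators")
  expect_error(project_config(weightings = "AC"), "weightings")
  expect_error(project_config(d = -1), "'d'")
  expect_error(project_config(sasa_cutoff = 2), "sasa_cutoff")
})

test_that("multi-project batches isolate failures", {
  f <- write_fasta_tmp(list(a = "HGGGWGQP"))
  dirp <- file.path(tempdir(), "multi")
  ok_cfg <- file.path(dirp, "ok.yaml")
  write_project_config(project_config(
    inputs = f, output_prefix = file.path(dirp, "ok")), ok_cfg)
  bad_cfg <- file.path(dirp, "bad.yaml")
  writeLines(c("schema: 1", "indices: [NOPE]"), bad_cfg)
  res <- run_multi(c(ok_cfg, bad_cfg))
  expect_equal(attr(res, "n_failed"), 1L)
  expect_true(file.exists(res[[ok_cfg]][["prot"]]))
  expect_true(isTRUE(res[[bad_cfg]]$failed))
  expect_match(res[[bad_cfg]]$error, "indices")
})

test_that("shannon relevance: constants, uniform bins, oracle agreement", {
  vals <- cbind(
    const = rep(5, 8),
    unif8 = 1:8,                       # one value per bin at n_bins = 8
    two   = rep(c(0, 1), 4)
  )
  tab <- descriptor_table(vals, paste0("p", 1:8), colnames(vals))
  rel <- shannon_relevance(tab, n_bins = 8)
  expect_equal(rel$entropy[rel$descriptor == "const"], 0)
  expect_equal(rel$entropy[rel$descriptor == "unif8"], 3)   # log2 8
  expect_equal(rel$entropy[rel$descriptor == "two"], 1)
  expect_equal(rel$descriptor[1], "unif8")                  # sorted desc

  set.seed(77)
  rnd <- matrix(stats::rnorm(20 * 15), 20, 15,
                dimnames = list(paste0("p", 1:20), paste0("d", 1:15)))
  tab2 <- descriptor_table(rnd, rownames(rnd), colnames(rnd))
  rel2 <- shannon_relevance(tab2, n_bins = 5)
  ref <- vapply(colnames(rnd), function(j)
    oracle_hist_entropy(rnd[, j], 5), numeric(1))
  expect_equal(stats::setNames(rel2$entropy, rel2$descriptor),
               ref[order(-ref, names(ref))])

  nat <- descriptor_table(cbind(x = c(NA_real_, NA_real_), y = c(1, 2)),
                          c("a", "b"), c("x", "y"))
  expect_warning(rel3 <- shannon_relevance(nat, 4), "all-sentinel")
  expect_equal(rel3$descriptor, "y")
})

test_that("distance matrices are metric and match brute force", {
  ident <- descriptor_table(matrix(1:4, 2, 2, byrow = TRUE,
                                   dimnames = list(c("a", "b"), c("x", "y"))),
                            c("a", "b"), c("x", "y"))
  ident[2, ] <- ident[1, ]
  expect_equal(max(distance_matrix(ident)), 0)

  two <- descriptor_table(cbind(d1 = c(1, 4), d2 = c(0, 0)),
                          c("a", "b"), c("d1", "d2"))
  expect_equal(distance_matrix(two, "euclidean")["a", "b"], 3)
  expect_equal(distance_matrix(two, "manhattan")["a", "b"], 3)

  set.seed(12)
  m <- matrix(stats::rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("p", 1:5), paste0("d", 1:20)))
  tab <- descriptor_table(m, rownames(m), colnames(m))
  for (metric in c("euclidean", "manhattan")) {
    dm <- distance_matrix(tab, metric)
    expect_equal(dm, t(dm))
    expect_equal(diag(dm), stats::setNames(rep(0, 5), rownames(m)))
    ref <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5)
      ref[i, j] <- if (metric == "euclidean")
        sqrt(sum((m[i, ] - m[j, ])^2)) else sum(abs(m[i, ] - m[j, ]))
    expect_equal(unname(dm), ref)
    # triangle inequality
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
  allna <- tab
  allna[, 1:19] <- NA_real_
  expect_error(suppressMessages(distance_matrix(allna)), "usable")
})

test_that("a mid-sized structure with hundreds of descriptors is fast", {
  m <- synthetic_structure("cluster", 200, seed = 3, core_size = 40)
  p <- write_model_pdb(m, tempfile(fileext = ".pdb"))
  cfg <- project_config(
    inputs = p,
    indices = c("HP", "z1", "z2", "wCO", "wNc", "wLRO"),
    weightings = c("NONE", "AC2", "ES"),
    groups = c("PRT", "INT", "SUP", "polar"),
    aggregators = protdescr::AGGREGATORS[1:10],
    zero_on_degenerate = TRUE,
    output_prefix = tempfile())
  elapsed <- system.time(r <- run_project(cfg))[["elapsed"]]
  tab <- read_descriptor_table(r[["prot"]])
  expect_equal(ncol(tab), 6L * 3L * 4L * 10L)
  expect_lt(elapsed, 60)
})
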