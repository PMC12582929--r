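meta2 <- make_meta(1L)  # WT_OD0.6_r1, MUT_OD0.6_r1

test_that("read_abundance_table parses values, missing cells, and enforces contracts", {
  meta_path <- write_tmp(c("sample_id\tstrain\tphase\treplicate",
                           "S1\tWT\tOD0.6\t1", "S2\tMUT\tOD0.6\t1"))
  tab <- write_tmp(c("feature_id\tS1\tS2", "glc\t5\t7", "pyr\t3\tNA"))
  m <- read_abundance_table(tab, "metabolomics", meta_path)
  expect_equal(unname(m$values["glc", ]), c(5, 7))
  expect_true(is.na(m$values["pyr", "S2"]))
  expect_identical(m$scale, "raw")

  bad <- write_tmp(c("feature_id\tS1\tS9", "glc\t5\t7"))
  expect_error(read_abundance_table(bad, "metabolomics", meta_path),
               "unknown sample S9")
  dup <- write_tmp(c("feature_id\tS1\tS2", "pyruvate\t1\t2",
                     "pyruvate\t3\t4"))
  expect_error(read_abundance_table(dup, "metabolomics", meta_path),
               "duplicate feature id: pyruvate")
  neg <- write_tmp(c("feature_id\tS1\tS2", "glc\t-5\t7"))
  expect_error(read_abundance_table(neg, "metabolomics", meta_path),
               "negative")
})

test_that("zero handling follows the modality convention", {
  meta_path <- write_tmp(c("sample_id\tstrain\tphase\treplicate",
                           "S1\tWT\tOD0.6\t1", "S2\tMUT\tOD0.6\t1"))
  tab <- write_tmp(c("feature_id\tS1\tS2", "f\t0\t7"))
  met <- read_abundance_table(tab, "metabolomics", meta_path)
  expect_identical(unname(met$values["f", "S1"]), 0)       # kept
  prot <- read_abundance_table(tab, "proteomics", meta_path)
  expect_true(is.na(prot$values["f", "S1"]))               # LFQ convention
})

test_that("internal-standard normalization divides per sample and flags the standard", {
  vals <- matrix(c(8, 6, 2, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("feat", "IS"), NULL))
  m <- make_am(vals, meta2, scale = "raw")
  norm <- normalize_internal_standard(m, "IS")
  expect_equal(unname(norm$values["feat", ]), c(8 / 2, 6 / 3))
  expect_equal(unname(norm$values["IS", ]), c(1, 1))
  expect_true(norm$is_standard[rownames(norm$values) == "IS"])
  expect_false("IS" %in% feature_ids(norm))  # excluded from statistics

  vals0 <- vals; vals0["IS", 1] <- 0
  m0 <- make_am(vals0, meta2, scale = "raw")
  expect_error(normalize_internal_standard(m0, "IS"),
               "internal standard zero in WT_OD0.6_r1")
  expect_error(normalize_internal_standard(m, "nope"), "not found")
})

test_that("wet-weight normalization divides per sample and validates weights", {
  m <- make_am(matrix(c(10, 9), nrow = 1), meta2, scale = "raw")
  w <- c(WT_OD0.6_r1 = 2, MUT_OD0.6_r1 = 3)
  norm <- normalize_wet_weight(m, w)
  expect_equal(unname(norm$values[1, ]), c(5, 3))
  expect_identical(norm$scale, "normalized")
  expect_error(normalize_wet_weight(m, c(WT_OD0.6_r1 = -1,
                                         MUT_OD0.6_r1 = 3)),
               "non-positive wet weight")
  expect_error(normalize_wet_weight(m, c(WT_OD0.6_r1 = 2)),
               "missing wet weight")
  # equal weights leave all pairwise sample ratios unchanged
  norm_eq <- normalize_wet_weight(m, c(WT_OD0.6_r1 = 2, MUT_OD0.6_r1 = 2))
  expect_equal(norm_eq$values[1, 1] / norm_eq$values[1, 2],
               m$values[1, 1] / m$values[1, 2])
})

test_that("normalization order relates by the per-sample weights and preserves missingness", {
  set.seed(42)
  vals <- matrix(stats::runif(20, 1, 10), nrow = 5,
                 dimnames = list(c(paste0("F", 1:4), "IS"), NULL))
  vals[2, 3] <- NA
  meta <- make_meta(2L)
  m <- make_am(vals, meta, scale = "raw")
  w <- stats::setNames(stats::runif(4, 0.5, 2), meta$sample_id)
  a <- normalize_wet_weight(normalize_internal_standard(m, "IS"), w)
  b <- normalize_internal_standard(normalize_wet_weight(m, w), "IS")
  # IS-after-wet-weight cancels the weights (the IS row was scaled too),
  # so the orders differ exactly by the per-sample weight factors
  expect_equal(a$values, sweep(b$values, 2L, w, "/"))
  expect_identical(is.na(a$values), is.na(m$values))
  expect_identical(is.na(b$values), is.na(m$values))
})

test_that("abundance tables round-trip bit-exactly", {
  set.seed(7)
  vals <- matrix(stats::rlnorm(24, 5, 2), nrow = 6)
  vals[c(2, 9, 17)] <- NA
  m <- make_am(vals, make_meta(2L))
  path <- tempfile(fileext = ".tsv")
  write_abundance_table(m, path)
  back <- read_abundance_table(path, "metabolomics", m$samples)
  expect_identical(back$values, m$values)
})

test_that("MaxQuant proteinGroups import filters flagged rows and maps zeros", {
  meta_path <- write_tmp(c("sample_id\tstrain\tphase\treplicate",
                           "A\tWT\tOD2.0\t1", "B\tMUT\tOD2.0\t1"))
  pg <- write_tmp(paste(
    c("Protein IDs\tReverse\tPotential contaminant\tLFQ intensity A\tLFQ intensity B",
      "P1\t\t\t100\t200",
      "P2\t+\t\t50\t60",
      "P3\t\t\t0\t300"), collapse = "\n"))
  m <- read_maxquant_protein_groups(pg, meta_path)
  expect_identical(rownames(m$values), c("P1", "P3"))
  expect_equal(unname(m$values["P1", ]), c(100, 200))
  expect_true(is.na(m$values["P3", "A"]))

  no_lfq <- write_tmp(c("Protein IDs\tReverse", "P1\t"))
  expect_error(read_maxquant_protein_groups(no_lfq, meta_path), "LFQ")
})

test_that("pathway annotations deduplicate and reject blank labels", {
  path <- write_tmp(c("feature_id\tpathway", "G6P\tGlycolysis",
                      "G6P\tPPP", "G6P\tGlycolysis"))
  ann <- read_pathway_annotations(path)
  expect_equal(sum(ann$feature_id == "G6P"), 2L)
  blank <- write_tmp(c("feature_id\tpathway", "G6P\t"))
  expect_error(read_pathway_annotations(blank), "empty pathway")
})
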