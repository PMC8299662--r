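test_that("expression tables read with annotation, and bad inputs error", {
  vals <- matrix(round(rnorm(8 * 6, 8), 3), 6, 8,
                 dimnames = list(sprintf("circ%02d", 1:6),
                                 c(paste0("T", 1:4), paste0("N", 1:4))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(vals, path)
  groups <- setNames(rep(c("tumor", "normal"), each = 4), colnames(vals))
  pairs <- setNames(rep(paste0("P", 1:4), 2), colnames(vals))
  em <- suppressMessages(
    read_expression_table(path, "circRNA", groups, pairs))
  expect_s3_class(em, "ExpressionMatrix")
  expect_equal(ncol(em$values), 8)
  expect_equal(em$kind, "circRNA")
  expect_equal(unname(table(em$groups)[c("normal", "tumor")]), c(4L, 4L),
               ignore_attr = TRUE)

  # header-only file
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("feature_id", colnames(vals)), collapse = "\t"), empty)
  expect_error(suppressMessages(
    read_expression_table(empty, "circRNA", groups)), "no features")

  # non-numeric cell named by feature and sample
  bad <- withr::local_tempfile(fileext = ".tsv")
  v2 <- vals
  writeLines(c(paste(c("feature_id", colnames(vals)), collapse = "\t"),
               paste(c("circ01", "oops", v2[1, -1]), collapse = "\t")), bad)
  expect_error(suppressMessages(
    read_expression_table(bad, "circRNA", groups)), "circ01.*T1")

  # group map referencing an unknown sample
  expect_error(suppressMessages(
    read_expression_table(path, "circRNA", c(groups, ghost = "tumor"))),
    "unknown sample")
  expect_error(suppressMessages(
    read_expression_table(path, "circRNA", groups[-1])), "without group")
})

test_that("duplicate probes collapse by max-mean or mean as configured", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2\ts3",
               "probeA\t1\t2\t3",
               "probeA\t4\t5\t6"), path)
  groups <- c(s1 = "tumor", s2 = "tumor", s3 = "normal")
  # row means are 2 and 5: max-mean keeps the second row
  em <- suppressMessages(read_expression_table(path, "mRNA", groups))
  expect_equal(nrow(em$values), 1)
  expect_equal(unname(em$values["probeA", ]), c(4, 5, 6))
  em2 <- suppressMessages(
    read_expression_table(path, "mRNA", groups, collapse = "mean"))
  expect_equal(unname(em2$values["probeA", ]), c(2.5, 3.5, 4.5))
})

test_that("write/read round trip preserves values and ordering exactly", {
  set.seed(42)
  vals <- matrix(rnorm(5 * 4) * 1e3, 5, 4,
                 dimnames = list(paste0("g", 5:1), paste0("s", 1:4)))
  vals[2, 3] <- NA
  em <- make_em(vals, rep(c("tumor", "normal"), each = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, path)
  back <- suppressMessages(
    read_expression_table(path, "mRNA", em$groups))
  expect_identical(rownames(back$values), rownames(vals))
  expect_identical(colnames(back$values), colnames(vals))
  expect_identical(back$values, vals)
})

test_that("log2 transform matches element-wise recomputation and is idempotent", {
  counts <- matrix(c(0, 7, 1, 3, 15, 31), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  em <- make_em(counts, c("tumor", "normal"))
  tr <- log2_transform(em, offset = 1)
  expect_equal(tr$values[1, 1], 0)   # log2(0 + 1)
  expect_equal(tr$values[2, 1], 3)   # log2(7 + 1)
  expect_equal(tr$values, log2(counts + 1))
  # flagged as already log-scale: bit-identical no-op
  expect_identical(log2_transform(tr, already_log = TRUE)$values, tr$values)
  neg <- make_em(matrix(c(-1, 2, 3, 4), 2, 2), c("tumor", "normal"))
  expect_error(log2_transform(neg), "negative")
})

test_that("probe-to-symbol mapping drops unmapped features and collapses", {
  vals <- matrix(1:15, 5, 3,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:3)))
  em <- make_em(vals * 1.0, c("tumor", "tumor", "normal"))
  mapping <- c(p1 = "GENEA", p2 = "GENEB", p3 = "GENEA")
  out <- suppressMessages(map_feature_ids(em, mapping, collapse = "mean"))
  expect_setequal(rownames(out$values), c("GENEA", "GENEB"))
  # p1 and p3 both map to GENEA: per-column mean of rows (1,4) = (2,7,12)
  expect_equal(unname(out$values["GENEA", ]), c(2, 7, 12))
  expect_error(map_feature_ids(em, character(0)), "empty")
  # identity mapping leaves the matrix unchanged
  idm <- setNames(rownames(vals), rownames(vals))
  expect_identical(suppressMessages(map_feature_ids(em, idm))$values,
                   em$values)
  # mapping can never increase the feature count
  for (k in 1:5) {
    mp <- setNames(sample(c("A", "B"), k, replace = TRUE),
                   sample(rownames(vals), k))
    expect_lte(nrow(suppressMessages(map_feature_ids(em, mp))$values),
               nrow(em$values))
  }
})

test_that("interaction, GMT, clinical and drug readers validate their formats", {
  # interaction table deduplicates
  ip <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tpartner_id", "miR-1\tcircA", "miR-1\tcircA",
               "miR-2\tcircB"), ip)
  tab <- suppressMessages(read_interaction_table(ip, "miRNA_circRNA"))
  expect_equal(nrow(tab$pairs), 2)
  bad_ip <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "x\ty"), bad_ip)
  expect_error(read_interaction_table(bad_ip), "header")

  # GMT
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("JAK_STAT\tdesc\tIL7R\tCCND2", "PATH2\tdesc\tmaoa\tPDGFB"), gmt)
  sets <- read_gene_sets_gmt(gmt)
  expect_equal(sort(sets$JAK_STAT), c("CCND2", "IL7R"))
  expect_true("MAOA" %in% sets$PATH2)  # uppercased on ingest
  bad_gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("OK\tdesc\tG1", "SHORT\tdesc"), bad_gmt)
  expect_error(read_gene_sets_gmt(bad_gmt), "line 2")

  # clinical
  cp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tos_time_days\tos_event", "s1\t100\t1",
               "s2\t-3\t0"), cp)
  expect_error(read_clinical_table(cp), "os_time")
  writeLines(c("sample_id\tos_time_days\tos_event", "s1\t100\t1",
               "s1\t50\t0"), cp)
  expect_error(read_clinical_table(cp), "duplicate")
  writeLines(c("sample_id\tos_time_days\tos_event", "s1\t100\t1",
               "s2\t50\t0"), cp)
  cl <- read_clinical_table(cp)
  expect_equal(cl$os_time, c(100, 50))

  # drug matrix requires the scale metadata line and round-trips
  dp <- withr::local_tempfile(fileext = ".tsv")
  ic50 <- matrix(c(1.5, NA, 2.5, 3.5), 2, 2,
                 dimnames = list(c("CL1", "CL2"), c("dA", "dB")))
  write_drug_matrix(drug_response_matrix(ic50, "ln_ic50"), dp)
  back <- read_drug_matrix(dp)
  expect_equal(back$ic50, ic50)
  expect_equal(back$scale, "ln_ic50")
  noscale <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_line\tdA", "CL1\t1.5"), noscale)
  expect_error(read_drug_matrix(noscale), "scale")
})

test_that("pairing keys must occur exactly once per group", {
  vals <- matrix(rnorm(8), 2, 4,
                 dimnames = list(c("g1", "g2"), c("t1", "t2", "n1", "n2")))
  groups <- c(t1 = "tumor", t2 = "tumor", n1 = "normal", n2 = "normal")
  expect_error(
    expression_matrix(vals, groups,
                      pairs = c(t1 = "P1", t2 = "P1", n1 = "P1", n2 = "P2")),
    "more than once")
  em <- expression_matrix(vals, groups,
                          pairs = c(t1 = "P1", t2 = "P2", n1 = "P1", n2 = "P2"))
  expect_s3_class(em, "ExpressionMatrix")
})
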