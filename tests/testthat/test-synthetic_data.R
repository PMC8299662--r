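small_cfg <- function(seed, de_fraction = 0.3, ...) {
  synthetic_config(seed,
                   n_features = c(circRNA = 60L, miRNA = 50L, mRNA = 80L),
                   de_fraction = de_fraction,
                   cohorts = list(
                     circ_a = list(kind = "circRNA", pairs = 4L),
                     circ_b = list(kind = "circRNA", pairs = 5L),
                     mrna_seq = list(kind = "mRNA", normal = 10L, tumor = 40L),
                     mirna_seq = list(kind = "miRNA", normal = 10L,
                                      tumor = 40L)),
                   n_background_pairs = 5L, ...)
}

test_that("the generator is bit-identical under a fixed seed", {
  s1 <- generate_synthetic_study(small_cfg(42))
  s2 <- generate_synthetic_study(small_cfg(42))
  expect_identical(s1$cohorts$circ_a$values, s2$cohorts$circ_a$values)
  expect_identical(s1$cohorts$mrna_seq$values, s2$cohorts$mrna_seq$values)
  expect_identical(s1$mc_pairs$pairs, s2$mc_pairs$pairs)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$drugs$ic50, s2$drugs$ic50)
  expect_identical(s1$manifest$de, s2$manifest$de)
  s3 <- generate_synthetic_study(small_cfg(43))
  expect_false(identical(s1$cohorts$circ_a$values, s3$cohorts$circ_a$values))
})

test_that("the manifest is consistent with the generated data", {
  st <- generate_synthetic_study(small_cfg(7))
  m <- st$manifest
  # planted features exist in the matrices of their kind
  expect_true(all(m$de$feature_id[m$de$kind == "circRNA"] %in%
                    rownames(st$cohorts$circ_a$values)))
  expect_true(all(m$de$feature_id[m$de$kind == "mRNA"] %in%
                    rownames(st$cohorts$mrna_seq$values)))
  # planted triplets satisfy the sign rule by construction
  t <- m$triplets
  expect_true(all(t$gene_direction == t$circ_direction))
  expect_true(all(t$gene_direction != t$mirna_direction))
  # and are wired in the interaction tables
  expect_true(all(paste(t$mirna_id, t$circ_id) %in%
                    paste(st$mc_pairs$pairs$mirna_id,
                          st$mc_pairs$pairs$partner_id)))
  expect_true(all(paste(t$mirna_id, t$gene_id) %in%
                    paste(st$mg_pairs$pairs$mirna_id,
                          st$mg_pairs$pairs$partner_id)))
  # prognostic and drug genes come from the planted network
  expect_true(all(m$prognostic$gene_id %in% t$gene_id))
  expect_true(all(m$drug_pairs$gene_id %in% m$prognostic$gene_id))
  # planted gene set contains the network genes
  expect_true(all(unique(t$gene_id) %in% st$gene_sets$SET_SYNTH_PLANTED))
})

test_that("a null generator plants nothing and bad configs error", {
  cfg <- small_cfg(3, de_fraction = 0)
  expr <- generate_expression(cfg)
  expect_equal(nrow(expr$de), 0)
  expect_error(synthetic_config(1, de_fraction = 0.1, effect_size = 0),
               "positive effect size")
  expect_error(synthetic_config(1, hazard_ratio = -2), "hazard ratio")
  expect_error(synthetic_config(), "mandatory")
  # more triplets than DE features of a kind
  cfg_over <- small_cfg(3, n_triplets = 50L)
  de <- generate_expression(cfg_over)$de
  expect_error(generate_interactions(cfg_over, de), "not enough")
})

test_that("planted log2 shifts are recovered empirically", {
  # paired design, effect 2.0, noise sd 0.5: the observed log2FC of planted
  # features should concentrate tightly around +-2
  hits <- 0; total <- 0
  for (seed in 1:20) {
    cfg <- synthetic_config(seed,
                            n_features = c(circRNA = 50L, miRNA = 5L, mRNA = 5L),
                            cohorts = list(circ_a = list(kind = "circRNA",
                                                         pairs = 5L)),
                            effect_size = 2, within_sd = 0.5)
    gen <- generate_expression(cfg)
    em <- gen$cohorts$circ_a
    planted <- gen$de[gen$de$kind == "circRNA", ]
    tumor <- names(em$groups)[em$groups == "tumor"]
    normal <- names(em$groups)[em$groups == "normal"]
    fc <- rowMeans(em$values[planted$feature_id, tumor, drop = FALSE]) -
      rowMeans(em$values[planted$feature_id, normal, drop = FALSE])
    signed <- fc * ifelse(planted$direction == "up", 1, -1)
    hits <- hits + sum(abs(signed - 2) <= 0.7)
    total <- total + nrow(planted)
  }
  expect_gte(hits / total, 0.95)
})

test_that("each decoy violates exactly one condition and is rejected", {
  st <- generate_synthetic_study(small_cfg(11))
  m <- st$manifest
  de <- m$de
  by_kind <- function(k) data.frame(feature_id = de$feature_id[de$kind == k],
                                    direction = de$direction[de$kind == k],
                                    stringsAsFactors = FALSE)
  net <- build_cerna_network(by_kind("circRNA"), by_kind("miRNA"),
                             by_kind("mRNA"), st$mc_pairs, st$mg_pairs)
  got <- paste(net$triplets$circ_id, net$triplets$mirna_id,
               net$triplets$gene_id)
  # all planted triplets recovered
  expect_setequal(got, paste(m$triplets$circ_id, m$triplets$mirna_id,
                             m$triplets$gene_id))
  # every decoy excluded, audited one by one
  for (i in seq_len(nrow(m$decoys))) {
    d <- m$decoys[i, ]
    expect_false(paste(d$circ_id, d$mirna_id, d$gene_id) %in% got,
                 label = sprintf("decoy %s (%s) leaked", i, d$type))
  }
})

test_that("survival times reflect the planted hazard and censoring rate", {
  worse_in_high <- 0
  for (seed in 1:20) {
    cfg <- small_cfg(seed, hazard_ratio = 3, censoring_rate = 0.4)
    expr <- generate_expression(cfg)
    em <- expr$cohorts$mrna_seq
    clin <- generate_clinical(cfg, em, prognostic_genes = "GS0001")
    cl <- clin$clinical
    if (seed <= 5) {
      # censoring within 5 points of the target on these small cohorts
      expect_lt(abs(mean(1 - cl$os_event) - 0.4), 0.25)
    }
    tumor <- cl$sample_id
    hi <- em$values["GS0001", tumor] > median(em$values["GS0001", tumor])
    med_hi <- median(cl$os_time[hi])
    med_lo <- median(cl$os_time[!hi])
    worse_in_high <- worse_in_high + (med_hi < med_lo)
  }
  expect_gte(worse_in_high, 18)
})

test_that("extreme censoring settings behave as declared", {
  cfg <- small_cfg(5, censoring_rate = 1)
  em <- generate_expression(cfg)$cohorts$mrna_seq
  cl <- generate_clinical(cfg, em)$clinical
  expect_true(all(cl$os_event == 0))
  km <- km_estimate(cl$os_time, cl$os_event)
  expect_true(all(km$survival == 1))
  cfg0 <- small_cfg(5, censoring_rate = 0)
  cl0 <- generate_clinical(cfg0, em)$clinical
  expect_true(all(cl0$os_event == 1))
})

test_that("censoring hits the configured rate on a large cohort", {
  cfg <- synthetic_config(9, censoring_rate = 0.6)
  em <- generate_expression(cfg)$cohorts$mrna_seq
  cl <- generate_clinical(cfg, em)$clinical
  expect_equal(nrow(cl), 450)
  expect_lt(abs(mean(1 - cl$os_event) - 0.6), 0.05)
})

test_that("written study files are deterministic and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_study(generate_synthetic_study(small_cfg(4)), d1)
  write_synthetic_study(generate_synthetic_study(small_cfg(4)), d2)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  expect_true(all(c("mirna_circ_pairs.tsv", "gene_sets.gmt", "clinical.tsv",
                    "drug_ic50.tsv", "manifest.json") %in% files))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})
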