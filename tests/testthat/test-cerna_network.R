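de_frame <- function(ids, dirs) {
  data.frame(feature_id = ids, direction = dirs, stringsAsFactors = FALSE)
}

test_that("network assembly applies interaction and sign constraints", {
  # planted toy: gene2 shares the miRNA but moves with it, so only gene1
  # completes a sponge triplet
  de_circ <- de_frame("circA", "down")
  de_mirna <- de_frame("miR1", "up")
  de_gene <- de_frame(c("gene1", "gene2"), c("down", "up"))
  mc <- interaction_table("miR1", "circA", "miRNA_circRNA")
  mg <- interaction_table(c("miR1", "miR1"), c("gene1", "gene2"), "miRNA_mRNA")
  net <- build_cerna_network(de_circ, de_mirna, de_gene, mc, mg)
  expect_equal(nrow(net$triplets), 1)
  expect_equal(net$triplets$gene_id, "gene1")
  expect_equal(net$triplets,
               brute_force_network(de_circ, de_mirna, de_gene, mc, mg))

  # empty interaction tables give an empty network
  empty_mc <- structure(list(kind = "miRNA_circRNA",
                             pairs = mc$pairs[0, ]), class = "InteractionTable")
  empty_mg <- structure(list(kind = "miRNA_mRNA",
                             pairs = mg$pairs[0, ]), class = "InteractionTable")
  net0 <- build_cerna_network(de_circ, de_mirna, de_gene, empty_mc, empty_mg)
  expect_equal(nrow(net0$triplets), 0)

  # correlation mode refuses to run without same-cohort expression
  expect_error(build_cerna_network(de_circ, de_mirna, de_gene, mc, mg,
                                   mode = "correlation"),
               "same-cohort expression")
})

test_that("every output triplet satisfies the sign rule and is significant DE", {
  set.seed(14)
  cfg <- synthetic_config(14, n_features = c(circRNA = 40L, miRNA = 30L,
                                             mRNA = 50L),
                          de_fraction = 0.4, n_triplets = 3L,
                          decoys_per_type = 1L, n_background_pairs = 10L)
  de <- generate_expression(cfg)$de
  net_in <- generate_interactions(cfg, de)
  by_kind <- function(k) de_frame(de$feature_id[de$kind == k],
                                  de$direction[de$kind == k])
  net <- build_cerna_network(by_kind("circRNA"), by_kind("miRNA"),
                             by_kind("mRNA"), net_in$mc_pairs, net_in$mg_pairs)
  t <- net$triplets
  expect_gt(nrow(t), 0)
  expect_true(all(t$gene_direction == t$circ_direction))
  expect_true(all(t$gene_direction != t$mirna_direction))
  sig <- de$feature_id
  expect_true(all(c(t$circ_id, t$mirna_id, t$gene_id) %in% sig))
})

test_that("network composition percentages follow count/total x 100 at 2 dp", {
  trip <- data.frame(circ_id = c("c1", "c1", "c2"),
                     mirna_id = c("m1", "m2", "m3"),
                     gene_id = c("g1", "g2", "g3"),
                     circ_direction = "down", mirna_direction = "up",
                     gene_direction = "down", stringsAsFactors = FALSE)
  # counts of the reference composition: 3 of 10 circRNAs is 30%,
  # 6 of 147 miRNAs is 4.08%, 157 of 4222 genes is 3.72%
  expect_equal(round(100 * 3 / 10, 2), 30)
  expect_equal(round(100 * 6 / 147, 2), 4.08)
  expect_equal(round(100 * 157 / 4222, 2), 3.72)
  s <- network_summary(cerna_network(trip),
                       c(circRNA = 10, miRNA = 147, mRNA = 4222))
  expect_equal(s$composition$n_network, c(2, 3, 3))
  expect_equal(s$composition$percent,
               round(100 * c(2 / 10, 3 / 147, 3 / 4222), 2))
  expect_equal(s$per_circ$n_genes[s$per_circ$circ_id == "c1"], 2L)

  s0 <- network_summary(cerna_network(trip[0, ]),
                        c(circRNA = 10, miRNA = 147, mRNA = 4222))
  expect_equal(s0$composition$n_network, c(0, 0, 0))
  expect_equal(s0$composition$percent, c(0, 0, 0))
})

test_that("per-circRNA subnetworks partition the network", {
  trip <- data.frame(circ_id = c("c1", "c1", "c2"),
                     mirna_id = c("m1", "m2", "m3"),
                     gene_id = c("g1", "g2", "g3"),
                     circ_direction = "down", mirna_direction = "up",
                     gene_direction = "down", stringsAsFactors = FALSE)
  net <- cerna_network(trip)
  s1 <- subnetwork_by_circ(net, "c1")
  s2 <- subnetwork_by_circ(net, "c2")
  expect_equal(nrow(s1$triplets) + nrow(s2$triplets), nrow(net$triplets))
  expect_equal(cerna_network(rbind(s1$triplets, s2$triplets)), net)
  # single-circRNA network maps to itself
  expect_equal(subnetwork_by_circ(s1, "c1"), s1)
  expect_warning(s3 <- subnetwork_by_circ(net, "nope"), "not in network")
  expect_equal(nrow(s3$triplets), 0)
})

test_that("subnetwork gene sets match the generator manifest per circRNA", {
  cfg <- synthetic_config(8, n_features = c(circRNA = 40L, miRNA = 30L,
                                            mRNA = 60L),
                          de_fraction = 0.4, n_triplets = 3L,
                          decoys_per_type = 1L)
  de <- generate_expression(cfg)$de
  net_in <- generate_interactions(cfg, de)
  by_kind <- function(k) de_frame(de$feature_id[de$kind == k],
                                  de$direction[de$kind == k])
  net <- build_cerna_network(by_kind("circRNA"), by_kind("miRNA"),
                             by_kind("mRNA"), net_in$mc_pairs, net_in$mg_pairs)
  for (circ in unique(net_in$triplets$circ_id)) {
    sub <- subnetwork_by_circ(net, circ)
    truth <- net_in$triplets$gene_id[net_in$triplets$circ_id == circ]
    expect_setequal(sub$triplets$gene_id, truth)
  }
})

test_that("host-gene overlap reports count and 2-dp percentage of DEGs", {
  degs <- sprintf("G%04d", 1:4222)
  r0 <- host_gene_overlap(c("X1", "X2"), degs)
  expect_equal(r0$n_overlap, 0)
  expect_equal(r0$percent, 0)
  r42 <- host_gene_overlap(degs[1:42], degs)
  expect_equal(r42$n_overlap, 42)
  expect_equal(r42$percent, 0.99)
  r7 <- host_gene_overlap(degs[1:7], degs)
  expect_equal(r7$percent, 0.17)
  # DE data frame input: only significant features count
  de <- de_frame(c("A", "B", "C"), c("up", "none", "down"))
  r <- host_gene_overlap(c("a", "c"), de)
  expect_equal(r$n_overlap, 2)
  expect_equal(r$n_de_genes, 2)
})

test_that("correlation filter keeps the required sign and handles degeneracy", {
  n <- 10
  x <- matrix(seq_len(n), 1, n, dimnames = list("miR1", paste0("s", 1:n)))
  y <- rbind(anti = rev(seq_len(n)), flat = rep(1, n))
  colnames(y) <- paste0("s", 1:n)
  ex <- make_em(x * 1.0, rep(c("tumor", "normal"), each = 5), kind = "miRNA")
  ey <- make_em(y * 1.0, rep(c("tumor", "normal"), each = 5), kind = "mRNA")
  pairs <- interaction_table(c("miR1", "miR1"), c("anti", "flat"),
                             "miRNA_mRNA")
  expect_warning(kept <- correlation_filter(ex, ey, pairs, 0.5, "negative"),
                 "undefined")
  expect_equal(kept$pairs$partner_id, "anti")

  # 6-sample pair against the hand rank formula rho = 1 - 6*sum(d^2)/(n^3-n)
  xv <- c(3.1, 0.2, 5.5, 2.2, 9.9, 4.4)
  yv <- c(2.0, 8.5, 1.1, 7.7, 0.5, 3.3)
  d <- rank(xv) - rank(yv)
  rho_hand <- 1 - 6 * sum(d^2) / (6^3 - 6)
  ex2 <- make_em(matrix(xv, 1, 6, dimnames = list("miR1", paste0("s", 1:6))),
                 rep(c("tumor", "normal"), each = 3), kind = "miRNA")
  ey2 <- make_em(matrix(yv, 1, 6, dimnames = list("gA", paste0("s", 1:6))),
                 rep(c("tumor", "normal"), each = 3), kind = "mRNA")
  p2 <- interaction_table("miR1", "gA", "miRNA_mRNA")
  kept2 <- correlation_filter(ex2, ey2, p2, abs(rho_hand) - 0.01, "negative")
  expect_equal(nrow(kept2$pairs), 1)
  kept3 <- correlation_filter(ex2, ey2, p2, abs(rho_hand) + 0.01, "negative")
  expect_equal(nrow(kept3$pairs), 0)

  short <- make_em(matrix(1:4, 1, 4, dimnames = list("miR1", paste0("s", 1:4))),
                   c("tumor", "tumor", "normal", "normal"), kind = "miRNA")
  expect_error(correlation_filter(short, short, p2), "5 shared samples")
})
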