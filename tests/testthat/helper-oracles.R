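# Independent oracles used across test files. These deliberately avoid the
# code paths they check: hypergeometric tails are summed from binomial
# coefficients, Spearman p-values from full permutation enumeration, the
# log-rank statistic from an explicit risk table, and BH from the raw
# step-up formula.

# P(X >= k) for k = 0..min(K, n), X ~ Hypergeometric(N, K, n), via explicit
# point-mass summation from binomial coefficients.
hyper_upper_tail_enum <- function(N, K, n) {
  ks <- 0:min(K, n)
  pmf <- numeric(length(ks))
  valid <- ks >= max(0, n - (N - K))
  pmf[valid] <- exp(lchoose(K, ks[valid]) + lchoose(N - K, n - ks[valid]) -
                      lchoose(N, n))
  rev(cumsum(rev(pmf)))
}

# All permutations of 1..n as a matrix (rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    cbind(i, m, deparse.level = 0)
  }))
}

# Two-sided exact permutation p for Spearman's rho: the fraction of rank
# permutations whose |rho| is at least the observed |rho|.
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  rho_obs <- stats::cor(rx, rank(y))
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, p))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Two-group log-rank chi-square from an explicit pooled risk table.
logrank_hand <- function(ta, ea, tb, eb) {
  times <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
  Oa <- 0; Ea <- 0; V <- 0
  for (u in times) {
    na <- sum(ta >= u); nb <- sum(tb >= u); n <- na + nb
    da <- sum(ta == u & ea == 1); db <- sum(tb == u & eb == 1); d <- da + db
    Oa <- Oa + da
    Ea <- Ea + d * na / n
    if (n > 1) V <- V + d * (na / n) * (nb / n) * (n - d) / (n - 1)
  }
  (Oa - Ea)^2 / V
}

# BH step-up written directly from its definition.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force ceRNA network: full cross-product of significant DE features,
# checking pair membership and the sign rule combination by combination.
brute_force_network <- function(de_circ, de_mirna, de_gene, mc_pairs, mg_pairs) {
  sig <- function(de) de[de$direction %in% c("up", "down"), ]
  dc <- sig(de_circ); dm <- sig(de_mirna); dg <- sig(de_gene)
  mc_key <- paste(mc_pairs$pairs$mirna_id, mc_pairs$pairs$partner_id)
  mg_key <- paste(mg_pairs$pairs$mirna_id, mg_pairs$pairs$partner_id)
  rows <- list()
  for (i in seq_len(nrow(dc))) for (j in seq_len(nrow(dm)))
    for (k in seq_len(nrow(dg))) {
      if (!paste(dm$feature_id[j], dc$feature_id[i]) %in% mc_key) next
      if (!paste(dm$feature_id[j], dg$feature_id[k]) %in% mg_key) next
      if (dg$direction[k] != dc$direction[i]) next
      if (dg$direction[k] == dm$direction[j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = dc$feature_id[i], mirna_id = dm$feature_id[j],
        gene_id = dg$feature_id[k], circ_direction = dc$direction[i],
        mirna_direction = dm$direction[j], gene_direction = dg$direction[k],
        stringsAsFactors = FALSE)
    }
  if (!length(rows))
    return(data.frame(circ_id = character(), mirna_id = character(),
                      gene_id = character(), circ_direction = character(),
                      mirna_direction = character(),
                      gene_direction = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$circ_id, out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# Minimal expression-matrix builder for unit tests.
make_em <- function(values, groups, pairs = NULL, kind = "mRNA") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, groups, pairs, kind)
}

# Write a feature-by-sample TSV the way external tools would provide it.
write_expr_tsv <- function(values, path, ids = rownames(values)) {
  df <- cbind(data.frame(feature_id = ids), as.data.frame(values))
  colnames(df) <- c("feature_id", colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
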