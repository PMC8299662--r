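#' Assemble a circRNA-miRNA-mRNA ceRNA network
#'
#' Joins differential-expression calls with miRNA-circRNA and miRNA-mRNA
#' interaction tables into sponge triplets. A triplet (circ, miRNA, gene) is
#' retained when all three members are significantly differentially
#' expressed, both interaction pairs exist, and — under the default
#' `sign_rule` mode — the expression directions are consistent with sponge
#' regulation: the gene moves with the circRNA and against the miRNA
#' (miRNAs repress their targets, and a circRNA sponging a miRNA de-represses
#' them, so circRNA and mRNA changes must be concordant while the miRNA
#' changes in the opposite direction).
#'
#' In `correlation` mode the interaction tables are additionally filtered by
#' [correlation_filter()] before the join, which requires expression of both
#' partners in the same cohort.
#'
#' @param de_circ,de_mirna,de_gene Data frames from
#'   [differential_expression()] (columns `feature_id`, `direction`).
#' @param mc_pairs `InteractionTable` of kind `miRNA_circRNA`.
#' @param mg_pairs `InteractionTable` of kind `miRNA_mRNA`.
#' @param mode `"sign_rule"` (default) or `"correlation"`.
#' @param expr_mirna,expr_circ,expr_gene Expression matrices sharing samples,
#'   required only for `mode = "correlation"`.
#' @param rho_threshold Minimum |Spearman rho| for `correlation` mode.
#' @return A `CeRNANetwork`: list with `triplets`, a data frame with columns
#'   `circ_id`, `mirna_id`, `gene_id` and the three direction columns, in
#'   canonical (lexicographic) order.
#' @export
build_cerna_network <- function(de_circ, de_mirna, de_gene,
                                mc_pairs, mg_pairs,
                                mode = c("sign_rule", "correlation"),
                                expr_mirna = NULL, expr_circ = NULL,
                                expr_gene = NULL, rho_threshold = 0.3) {
  mode <- match.arg(mode)
  stopifnot(inherits(mc_pairs, "InteractionTable"),
            inherits(mg_pairs, "InteractionTable"))
  if (mc_pairs$kind != "miRNA_circRNA" || mg_pairs$kind != "miRNA_mRNA")
    stop("interaction tables of the wrong kind")
  if (mode == "correlation") {
    if (is.null(expr_mirna) || is.null(expr_circ) || is.null(expr_gene))
      stop("mode 'correlation' requires same-cohort expression for all partners")
    mc_pairs <- correlation_filter(expr_mirna, expr_circ, mc_pairs,
                                   rho_threshold, sign = "negative")
    mg_pairs <- correlation_filter(expr_mirna, expr_gene, mg_pairs,
                                   rho_threshold, sign = "negative")
  }

  circ_dir <- de_direction_map(de_circ)
  mirna_dir <- de_direction_map(de_mirna)
  gene_dir <- de_direction_map(de_gene)

  mc <- mc_pairs$pairs
  mg <- mg_pairs$pairs
  mc <- mc[mc$mirna_id %in% names(mirna_dir) &
             mc$partner_id %in% names(circ_dir), , drop = FALSE]
  mg <- mg[mg$mirna_id %in% names(mirna_dir) &
             mg$partner_id %in% names(gene_dir), , drop = FALSE]
  if (nrow(mc) == 0 || nrow(mg) == 0) return(cerna_network(empty_triplets()))

  joined <- merge(
    data.frame(mirna_id = mc$mirna_id, circ_id = mc$partner_id,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = mg$mirna_id, gene_id = mg$partner_id,
               stringsAsFactors = FALSE),
    by = "mirna_id")
  if (nrow(joined) == 0) return(cerna_network(empty_triplets()))
  joined$circ_direction <- unname(circ_dir[joined$circ_id])
  joined$mirna_direction <- unname(mirna_dir[joined$mirna_id])
  joined$gene_direction <- unname(gene_dir[joined$gene_id])
  keep <- joined$gene_direction == joined$circ_direction &
    joined$gene_direction != joined$mirna_direction
  trip <- joined[keep, c("circ_id", "mirna_id", "gene_id",
                         "circ_direction", "mirna_direction",
                         "gene_direction"), drop = FALSE]
  cerna_network(trip)
}

# Significant features -> named direction vector.
de_direction_map <- function(de) {
  stopifnot(is.data.frame(de), all(c("feature_id", "direction") %in% colnames(de)))
  sig <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  stats::setNames(sig$direction, sig$feature_id)
}

empty_triplets <- function() {
  data.frame(circ_id = character(), mirna_id = character(),
             gene_id = character(), circ_direction = character(),
             mirna_direction = character(), gene_direction = character(),
             stringsAsFactors = FALSE)
}

#' @rdname build_cerna_network
#' @param triplets Data frame of triplets (see return value).
#' @export
cerna_network <- function(triplets) {
  need <- colnames(empty_triplets())
  stopifnot(is.data.frame(triplets), all(need %in% colnames(triplets)))
  triplets <- unique(triplets[, need, drop = FALSE])
  ord <- order(triplets$circ_id, triplets$mirna_id, triplets$gene_id)
  triplets <- triplets[ord, , drop = FALSE]
  rownames(triplets) <- NULL
  structure(list(triplets = triplets), class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  t <- x$triplets
  cat(sprintf("CeRNANetwork: %d triplets (%d circRNAs, %d miRNAs, %d genes)\n",
              nrow(t), length(unique(t$circ_id)), length(unique(t$mirna_id)),
              length(unique(t$gene_id))))
  invisible(x)
}

#' Filter interaction pairs by Spearman correlation
#'
#' Retains pairs whose Spearman correlation across shared samples has the
#' required sign and magnitude. Pairs whose correlation is undefined (a
#' constant profile) are dropped with a warning.
#'
#' @param expr_x Expression matrix holding the miRNA side of each pair.
#' @param expr_y Expression matrix holding the partner side.
#' @param pairs An `InteractionTable`.
#' @param rho_threshold Minimum |rho| (default 0.3).
#' @param sign `"negative"` or `"positive"`.
#' @return The filtered `InteractionTable`.
#' @export
correlation_filter <- function(expr_x, expr_y, pairs, rho_threshold = 0.3,
                               sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  stopifnot(inherits(expr_x, "ExpressionMatrix"),
            inherits(expr_y, "ExpressionMatrix"),
            inherits(pairs, "InteractionTable"))
  shared <- intersect(colnames(expr_x$values), colnames(expr_y$values))
  if (length(shared) < 5) stop("need >= 5 shared samples for correlation")
  df <- pairs$pairs
  keep <- logical(nrow(df))
  n_degenerate <- 0L
  for (i in seq_len(nrow(df))) {
    if (!(df$mirna_id[i] %in% rownames(expr_x$values)) ||
        !(df$partner_id[i] %in% rownames(expr_y$values))) next
    x <- expr_x$values[df$mirna_id[i], shared]
    y <- expr_y$values[df$partner_id[i], shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 5) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    keep[i] <- abs(rho) >= rho_threshold &&
      ((sign == "negative" && rho < 0) || (sign == "positive" && rho > 0))
  }
  if (n_degenerate > 0)
    warning(sprintf("%d pair(s) dropped: correlation undefined (constant profile)",
                    n_degenerate))
  out <- df[keep, , drop = FALSE]
  if (nrow(out) == 0)
    return(structure(list(kind = pairs$kind,
                          pairs = df[0, , drop = FALSE]),
                     class = "InteractionTable"))
  interaction_table(out$mirna_id, out$partner_id, pairs$kind)
}

#' Summarise ceRNA network composition
#'
#' Absolute counts and percentages of differentially expressed features of
#' each RNA kind that entered the network, plus per-circRNA unique gene
#' counts.
#'
#' @param net A `CeRNANetwork`.
#' @param de_counts Named numeric vector with elements `circRNA`, `miRNA`,
#'   `mRNA`: the total number of DE features of each kind.
#' @return List with `composition` (kind, n_network, n_de, percent to 2
#'   decimals) and `per_circ` (circ_id, n_genes).
#' @export
network_summary <- function(net, de_counts) {
  stopifnot(inherits(net, "CeRNANetwork"),
            all(c("circRNA", "miRNA", "mRNA") %in% names(de_counts)))
  if (any(de_counts[c("circRNA", "miRNA", "mRNA")] <= 0))
    stop("de_counts must be positive")
  t <- net$triplets
  n <- c(circRNA = length(unique(t$circ_id)),
         miRNA = length(unique(t$mirna_id)),
         mRNA = length(unique(t$gene_id)))
  comp <- data.frame(kind = names(n), n_network = unname(n),
                     n_de = unname(de_counts[names(n)]),
                     stringsAsFactors = FALSE)
  comp$percent <- round(100 * comp$n_network / comp$n_de, 2)
  per_circ <- if (nrow(t)) {
    cnt <- tapply(t$gene_id, t$circ_id, function(g) length(unique(g)))
    data.frame(circ_id = names(cnt), n_genes = as.integer(cnt),
               stringsAsFactors = FALSE)
  } else {
    data.frame(circ_id = character(), n_genes = integer())
  }
  rownames(per_circ) <- NULL
  list(composition = comp, per_circ = per_circ[order(-per_circ$n_genes,
                                                     per_circ$circ_id), ,
                                               drop = FALSE])
}

#' Extract the subnetwork of one circRNA
#'
#' @param net A `CeRNANetwork`.
#' @param circ_id circRNA identifier.
#' @return A `CeRNANetwork` restricted to triplets of that circRNA (empty,
#'   with a warning, when the circRNA is absent).
#' @export
subnetwork_by_circ <- function(net, circ_id) {
  stopifnot(inherits(net, "CeRNANetwork"))
  t <- net$triplets[net$triplets$circ_id == circ_id, , drop = FALSE]
  if (nrow(t) == 0)
    warning("circRNA '", circ_id, "' not in network; returning empty network")
  cerna_network(t)
}

#' Overlap between circRNA host genes and differentially expressed genes
#'
#' Counts how many host genes of the differential circRNAs are themselves
#' differentially expressed, as an absolute count and as a percentage of all
#' DEGs. A small percentage indicates that circRNA dysregulation is not
#' explained by host-gene transcription in cis.
#'
#' @param host_genes Character vector of host-gene symbols.
#' @param de_genes Either a [differential_expression()] data frame (its
#'   significant features are used) or a character vector of DEG ids.
#' @return List with `n_overlap`, `n_de_genes` and `percent` (2 decimals).
#' @export
host_gene_overlap <- function(host_genes, de_genes) {
  deg <- if (is.data.frame(de_genes)) names(de_direction_map(de_genes))
  else unique(as.character(de_genes))
  n <- length(intersect(toupper(unique(host_genes)), toupper(deg)))
  pct <- if (length(deg)) round(100 * n / length(deg), 2) else 0
  list(n_overlap = n, n_de_genes = length(deg), percent = pct)
}

#' Write a ceRNA network edge list to TSV
#' @param net A `CeRNANetwork`.
#' @param path Output path.
#' @export
write_cerna_network <- function(net, path) {
  utils::write.table(net$triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
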