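#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average-rank tie handling. The p-value is two-sided:
#' for n <= 10 without ties it comes from the exact permutation distribution
#' of the rank statistic; otherwise from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value in
#'   either vector are dropped, after which at least 3 pairs must remain.
#' @return List with `rho`, `p_value`, `n` and `degenerate` (`TRUE` when one
#'   vector is constant so the correlation is undefined; `rho` and `p_value`
#'   are then `NA`).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p_value = min(p, 1), n = n, degenerate = FALSE)
}

#' Screen gene-drug associations across cell lines
#'
#' Spearman correlation between each gene's expression and each drug's IC50
#' across shared cell lines, pairwise-complete over missing IC50 entries,
#' with Benjamini-Hochberg FDR control over the whole screen. A negative
#' correlation (higher expression, lower IC50) marks a sensitizing
#' association, a positive one a resistance association.
#'
#' @param expr Gene expression across cell lines: an [expression_matrix()]
#'   or a plain numeric matrix (genes x cell lines).
#' @param drugs A `DrugResponseMatrix` (see [read_drug_matrix()]).
#' @param gene_ids Genes to screen; default all rows of `expr`.
#' @param fdr_threshold Strict FDR cutoff for flagging (default 0.05).
#' @param fdr_grouping `"global"` (BH across all gene x drug pairs, the
#'   default) or `"per_gene"` (BH within each gene's drug panel).
#' @return Data frame: `gene_id`, `drug_id`, `n`, `rho`, `p_value`, `fdr`,
#'   `direction` (`sensitizing` / `resistant`), `flagged`, `skip_reason`.
#'   Degenerate or under-sampled pairs carry a skip reason and are excluded
#'   from the BH adjustment.
#' @export
drug_gene_screen <- function(expr, drugs, gene_ids = NULL,
                             fdr_threshold = 0.05,
                             fdr_grouping = c("global", "per_gene")) {
  fdr_grouping <- match.arg(fdr_grouping)
  stopifnot(inherits(drugs, "DrugResponseMatrix"))
  vals <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  stopifnot(is.matrix(vals))
  if (is.null(gene_ids)) gene_ids <- rownames(vals)
  lines <- intersect(colnames(vals), rownames(drugs$ic50))
  if (!length(lines)) stop("no shared cell lines between expression and IC50 data")
  lines <- sort(lines)

  rows <- list()
  for (g in gene_ids) {
    if (!g %in% rownames(vals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, drug_id = NA_character_, n = NA_integer_,
        rho = NA_real_, p_value = NA_real_,
        skip_reason = "not in expression matrix", stringsAsFactors = FALSE)
      next
    }
    for (d in colnames(drugs$ic50)) {
      x <- vals[g, lines]
      y <- drugs$ic50[lines, d]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, drug_id = d, n = sum(ok), rho = NA_real_,
          p_value = NA_real_, skip_reason = "fewer than 3 complete pairs",
          stringsAsFactors = FALSE)
        next
      }
      sc <- spearman_cor(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, drug_id = d, n = sc$n, rho = sc$rho,
        p_value = sc$p_value,
        skip_reason = if (sc$degenerate) "constant expression or IC50"
        else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tested <- is.na(out$skip_reason)
  out$fdr <- NA_real_
  if (any(tested)) {
    if (fdr_grouping == "global") {
      out$fdr[tested] <- bh_adjust(out$p_value[tested])
    } else {
      for (g in unique(out$gene_id[tested])) {
        idx <- tested & out$gene_id == g
        out$fdr[idx] <- bh_adjust(out$p_value[idx])
      }
    }
  }
  out$direction <- ifelse(!tested | is.na(out$rho), NA_character_,
                          ifelse(out$rho < 0, "sensitizing", "resistant"))
  out$flagged <- tested & !is.na(out$fdr) & out$fdr < fdr_threshold
  out <- out[, c("gene_id", "drug_id", "n", "rho", "p_value", "fdr",
                 "direction", "flagged", "skip_reason")]
  rownames(out) <- NULL
  out
}

#' Write a drug-association screen to TSV
#' @param assoc Data frame from [drug_gene_screen()].
#' @param path Output path.
#' @export
write_drug_screen <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
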