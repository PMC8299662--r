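#' Differential-expression threshold configuration
#'
#' Thresholds and test choice for the tumor-versus-normal screen. A feature
#' is called differentially expressed when its p-value is strictly below
#' `p_threshold` and its |log2 fold change| strictly above `fc_threshold`
#' (so boundary values are never significant).
#'
#' @param p_threshold Significance cutoff on the p-value (default 0.05).
#' @param fc_threshold Cutoff on |log2FC| (default 1, i.e. a 2-fold change).
#' @param use_adjusted_p If `TRUE`, direction calls use the BH-adjusted p
#'   instead of the raw p. Raw p is the default: the conventional screen
#'   filters on raw p while still reporting the adjusted value.
#' @param de_method `"auto"` (paired t when complete pairing is available,
#'   Welch t otherwise), `"welch_t"`, `"student_t"` or `"paired_t"`.
#' @return A `ThresholdConfig` list.
#' @export
threshold_config <- function(p_threshold = 0.05, fc_threshold = 1,
                             use_adjusted_p = FALSE,
                             de_method = c("auto", "welch_t", "student_t",
                                           "paired_t")) {
  de_method <- match.arg(de_method)
  if (p_threshold <= 0 || fc_threshold <= 0)
    stop("thresholds must be > 0")
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 use_adjusted_p = use_adjusted_p, de_method = de_method),
            class = "ThresholdConfig")
}

#' Tumor-versus-normal differential expression
#'
#' Per-feature two-group comparison on the log2 scale. log2FC is
#' mean(log2 tumor) - mean(log2 normal); the p-value comes from the
#' configured t-test. Benjamini-Hochberg adjusted p-values are always
#' reported alongside the raw p.
#'
#' Features with missing values in more than `max_missing_frac` of samples
#' are dropped before testing. Features whose within-group variance is zero
#' in both groups cannot be t-tested; they receive p = 0 when the group means
#' differ and p = 1 when they are equal, with a warning.
#'
#' @param em An [expression_matrix()] (values already log2 scale).
#' @param config A [threshold_config()].
#' @param dataset_id Label recorded in the `dataset_id` column.
#' @param max_missing_frac Features missing in more than this fraction of
#'   samples are dropped (default 0.2).
#' @return Data frame with columns `feature_id`, `log2fc`, `p_value`,
#'   `adj_p`, `direction` (`up` / `down` / `none`), `dataset_id`.
#' @export
differential_expression <- function(em, config = threshold_config(),
                                    dataset_id = "dataset",
                                    max_missing_frac = 0.2) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  method <- config$de_method
  tumor <- names(em$groups)[em$groups == "tumor"]
  normal <- names(em$groups)[em$groups == "normal"]
  if (length(tumor) < 2 || length(normal) < 2)
    stop("need >= 2 samples per group")
  if (method == "auto")
    method <- if (!is.null(em$pairs) &&
                  setequal(em$pairs[tumor], em$pairs[normal]))
      "paired_t" else "welch_t"
  if (method == "paired_t") {
    if (is.null(em$pairs)) stop("paired_t requires pair ids")
    keys <- intersect(em$pairs[tumor], em$pairs[normal])
    if (length(keys) < 2) stop("paired_t requires >= 2 complete pairs")
    tumor <- tumor[match(keys, em$pairs[tumor])]
    normal <- normal[match(keys, em$pairs[normal])]
  }

  vals <- em$values
  miss_frac <- rowMeans(is.na(vals[, c(tumor, normal), drop = FALSE]))
  dropped <- sum(miss_frac > max_missing_frac)
  if (dropped > 0) {
    message(sprintf("dropped %d feature(s) missing in > %.0f%% of samples",
                    dropped, 100 * max_missing_frac))
    vals <- vals[miss_frac <= max_missing_frac, , drop = FALSE]
  }
  if (nrow(vals) == 0) stop("no features left after missing-value filter")

  n_degenerate <- 0L
  res <- vapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, tumor]
    y <- vals[i, normal]
    if (method == "paired_t") {
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 2) return(c(NA_real_, NA_real_))
      d <- x - y
      fc <- mean(d)
      if (stats::sd(d) == 0) {
        n_degenerate <<- n_degenerate + 1L
        return(c(fc, if (fc == 0) 1 else 0))
      }
      p <- stats::t.test(x, y, paired = TRUE)$p.value
      return(c(fc, p))
    }
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(c(NA_real_, NA_real_))
    fc <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      n_degenerate <<- n_degenerate + 1L
      return(c(fc, if (fc == 0) 1 else 0))
    }
    p <- stats::t.test(x, y, var.equal = (method == "student_t"))$p.value
    c(fc, p)
  }, numeric(2))
  if (n_degenerate > 0)
    warning(sprintf("%d feature(s) with zero variance in both groups; p set to 0/1",
                    n_degenerate))

  out <- data.frame(feature_id = rownames(vals),
                    log2fc = res[1, ], p_value = res[2, ],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$p_value), , drop = FALSE]
  out$adj_p <- bh_adjust(out$p_value)
  p_used <- if (isTRUE(config$use_adjusted_p)) out$adj_p else out$p_value
  out$direction <- classify_direction(out$log2fc, p_used, config)
  out$dataset_id <- dataset_id
  rownames(out) <- NULL
  out
}

#' Classify differential-expression direction
#'
#' Strict-inequality rule: `up` when p < p_threshold and log2FC >
#' fc_threshold; `down` when p < p_threshold and log2FC < -fc_threshold;
#' `none` otherwise (values exactly at a threshold are not significant).
#'
#' @param log2fc,p Numeric vectors of equal length.
#' @param config A [threshold_config()].
#' @return Character vector in `{"up", "down", "none"}`.
#' @export
classify_direction <- function(log2fc, p, config = threshold_config()) {
  stopifnot(length(log2fc) == length(p))
  out <- rep("none", length(p))
  sig <- !is.na(p) & !is.na(log2fc) & p < config$p_threshold
  out[sig & log2fc > config$fc_threshold] <- "up"
  out[sig & log2fc < -config$fc_threshold] <- "down"
  out
}

#' Fisher exact test for overlap of two feature lists
#'
#' One-sided (enrichment) Fisher exact test of whether two
#' differential-expression lists drawn from a common universe overlap more
#' than expected by chance: the p-value is the hypergeometric upper tail
#' P(X >= observed overlap).
#'
#' @param list_a,list_b Character vectors of feature ids; must be subsets of
#'   `universe`.
#' @param universe Character vector of all testable features.
#' @return An `OverlapResult` list: `n_overlap`, `n_a_only`, `n_b_only`,
#'   `n_universe`, `odds_ratio` (cross-product ratio, with 0.5 added to every
#'   cell when any cell is zero) and one-sided `p_value`.
#' @export
overlap_significance <- function(list_a, list_b, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  if (!all(list_a %in% universe) || !all(list_b %in% universe))
    stop("lists must be subsets of the universe")
  n11 <- length(intersect(list_a, list_b))
  n12 <- length(list_a) - n11
  n21 <- length(list_b) - n11
  n22 <- length(universe) - n11 - n12 - n21
  p <- stats::phyper(n11 - 1, length(list_a), length(universe) - length(list_a),
                     length(list_b), lower.tail = FALSE)
  cells <- c(n11, n12, n21, n22)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  structure(list(n_overlap = n11, n_a_only = n12, n_b_only = n21,
                 n_universe = length(universe), odds_ratio = or, p_value = p),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(paste0("Overlap: %d shared, %d A-only, %d B-only, universe %d\n",
                     "odds ratio %.3g, one-sided Fisher p = %.3g\n"),
              x$n_overlap, x$n_a_only, x$n_b_only, x$n_universe,
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, preserving input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Write differential-expression results to TSV
#' @param de Data frame from [differential_expression()].
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
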