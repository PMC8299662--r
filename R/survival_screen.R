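#' Split samples at the median expression value
#'
#' Dichotomizes a cohort into `high` (strictly above the median) and `low`
#' (at or below the median) expression groups. Samples tied with the median
#' therefore go to `low`, so that "high" always means strictly above the
#' cohort median.
#'
#' @param x Named (or unnamed) numeric vector of per-sample expression,
#'   length >= 4.
#' @return Character vector of `"high"` / `"low"` labels, same names/order
#'   as `x`.
#' @export
median_split <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need >= 4 samples for a median split")
  if (max(x) == min(x)) stop("degenerate split: constant expression")
  med <- stats::median(x)
  lab <- ifelse(x > med, "high", "low")
  if (!all(c("high", "low") %in% lab))
    stop("degenerate split: one group empty")
  lab
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with `d_i`
#' deaths among `n_i` at risk. Implemented via [survival::survfit()].
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @return A `KMCurve` data frame: `time`, `n_risk`, `n_event`, `survival`,
#'   one row per distinct observed time. `S` starts at 1 and steps down only
#'   at event times.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival curves:
#' chi-square = (O - E)^2 / Var with the hypergeometric variance summed over
#' the pooled risk table, referred to a 1-df chi-square distribution.
#' Symmetric in group order. Implemented via [survival::survdiff()].
#'
#' @param times_a,events_a Follow-up times and 0/1 event indicators, group A.
#' @param times_b,events_b Same for group B.
#' @return List with `chi_square` and `p_value`. When neither group has any
#'   event the test is undefined; chi-square 0 and p 1 are returned with a
#'   warning.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(list(chi_square = 0, p_value = 1))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Median-split log-rank screen of genes against overall survival
#'
#' For each gene, samples with both expression and clinical data are split at
#' the median expression ([median_split()]) and the two groups compared by
#' log-rank test ([logrank_test()]). Genes that cannot be tested (absent from
#' the matrix, too few samples, constant expression) are reported with an
#' explicit skip reason instead of being silently dropped.
#'
#' @param em An [expression_matrix()] (tumor cohort).
#' @param clinical Data frame from [read_clinical_table()].
#' @param gene_ids Genes to screen; default all matrix features.
#' @param p_threshold Strict significance cutoff on the log-rank p (default
#'   0.05).
#' @return Data frame: `gene_id`, `n_high`, `n_low`, `chi_square`,
#'   `p_value`, `significant`, `skip_reason`.
#' @export
prognostic_screen <- function(em, clinical, gene_ids = NULL,
                              p_threshold = 0.05) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(gene_ids)) gene_ids <- rownames(em$values)
  shared <- intersect(colnames(em$values), clinical$sample_id)
  if (!length(shared)) stop("no samples shared between expression and clinical data")
  if (length(shared) < 10) stop("need >= 10 samples with expression and survival")
  shared <- sort(shared)
  cl <- clinical[match(shared, clinical$sample_id), ]

  rows <- lapply(gene_ids, function(g) {
    row <- data.frame(gene_id = g, n_high = NA_integer_, n_low = NA_integer_,
                      chi_square = NA_real_, p_value = NA_real_,
                      significant = FALSE, skip_reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (!g %in% rownames(em$values)) {
      row$skip_reason <- "not in expression matrix"
      return(row)
    }
    x <- em$values[g, shared]
    ok <- !is.na(x)
    if (sum(ok) < 10) {
      row$skip_reason <- "fewer than 10 usable samples"
      return(row)
    }
    lab <- tryCatch(median_split(x[ok]), error = function(e) NULL)
    if (is.null(lab)) {
      row$skip_reason <- "degenerate median split"
      return(row)
    }
    t_hi <- cl$os_time[ok][lab == "high"]
    e_hi <- cl$os_event[ok][lab == "high"]
    t_lo <- cl$os_time[ok][lab == "low"]
    e_lo <- cl$os_event[ok][lab == "low"]
    lr <- suppressWarnings(logrank_test(t_hi, e_hi, t_lo, e_lo))
    row$n_high <- sum(lab == "high")
    row$n_low <- sum(lab == "low")
    row$chi_square <- lr$chi_square
    row$p_value <- lr$p_value
    row$significant <- !is.na(lr$p_value) && lr$p_value < p_threshold
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a prognostic screen table to TSV
#' @param screen Data frame from [prognostic_screen()].
#' @param path Output path.
#' @export
write_survival_screen <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
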