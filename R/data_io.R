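#' Construct an expression matrix with sample annotation
#'
#' The central data container of the pipeline: a log2-scale feature-by-sample
#' abundance matrix with per-sample group labels (`tumor` / `normal`) and an
#' optional pairing key identifying tumor/normal samples from the same
#' patient. All statistical stages operate on this object.
#'
#' @param values Numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames). Values are on the log2 scale; `NA` marks
#'   missing measurements. Infinite values are rejected.
#' @param groups Character vector of `"tumor"` / `"normal"` labels, either
#'   named by sample id or in column order.
#' @param pairs Optional character vector of pairing keys (same key = same
#'   patient), named by sample id or in column order. When present, every key
#'   must occur exactly once per group.
#' @param kind Feature kind: `"circRNA"`, `"miRNA"` or `"mRNA"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `groups`, `pairs`, `kind`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, rep(c("tumor", "normal"), each = 2), kind = "mRNA")
#' dim(em$values)
#' @export
expression_matrix <- function(values, groups, pairs = NULL,
                              kind = c("circRNA", "miRNA", "mRNA")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(is.infinite(values)))
    stop("non-finite expression values; missing data must be NA, not Inf")
  samples <- colnames(values)

  groups <- align_sample_vector(groups, samples, "groups")
  if (!all(groups %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'")
  if (!is.null(pairs)) {
    pairs <- align_sample_vector(pairs, samples, "pairs")
    for (g in unique(groups)) {
      k <- pairs[groups == g]
      if (anyDuplicated(k))
        stop("pair key appears more than once in group '", g, "'")
    }
    if (!setequal(pairs[groups == "tumor"], pairs[groups == "normal"]))
      warning("pair keys do not match across groups; incomplete pairs present")
  }
  structure(list(values = values, groups = groups, pairs = pairs, kind = kind),
            class = "ExpressionMatrix")
}

# Align a per-sample annotation vector to the matrix columns.
align_sample_vector <- function(x, samples, what) {
  x <- as.character(x)
  if (!is.null(names(x))) {
    missing <- setdiff(samples, names(x))
    if (length(missing))
      stop("no ", what, " entry for sample(s): ", paste(missing, collapse = ", "))
    unknown <- setdiff(names(x), samples)
    if (length(unknown))
      stop("unknown sample(s) in ", what, ": ", paste(unknown, collapse = ", "))
    x <- x[samples]
  } else if (length(x) != length(samples)) {
    stop("'", what, "' must have one entry per sample")
  } else {
    names(x) <- samples
  }
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples (%d tumor / %d normal)%s\n",
              x$kind, nrow(x$values), ncol(x$values),
              sum(x$groups == "tumor"), sum(x$groups == "normal"),
              if (is.null(x$pairs)) "" else ", paired"))
  invisible(x)
}

#' Read a tab-separated expression table
#'
#' Reads a TSV whose first column (`feature_id`) holds feature identifiers and
#' whose remaining columns are samples, attaches group/pair annotation and
#' collapses duplicate feature rows.
#'
#' @param path Path to the TSV file.
#' @param feature_kind `"circRNA"`, `"miRNA"` or `"mRNA"`.
#' @param group_map Named character vector mapping sample id to
#'   `"tumor"`/`"normal"`. Every sample in the map must exist in the table and
#'   every table sample must be covered.
#' @param pair_map Optional named character vector mapping sample id to a
#'   pairing key.
#' @param collapse Duplicate-feature collapse policy: `"max_mean"` keeps the
#'   row with the highest mean expression (the usual microarray convention),
#'   `"mean"` averages rows per column.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, feature_kind, group_map,
                                  pair_map = NULL,
                                  collapse = c("max_mean", "mean")) {
  collapse <- match.arg(collapse)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression table needs a feature column and >=1 sample")
  if (nrow(tab) == 0) stop("no features in ", path)
  ids <- tab[[1]]
  samples <- colnames(tab)[-1]
  vals <- matrix(NA_real_, nrow(tab), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    raw <- tab[[j + 1]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw) | raw %in% c("", "NA", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                   raw[bad[1]], ids[bad[1]], samples[j]))
    vals[, j] <- num
  }
  rownames(vals) <- make.unique(ids)
  vals <- collapse_duplicate_rows(vals, ids, collapse)

  if (is.null(names(group_map))) stop("'group_map' must be named by sample id")
  unknown <- setdiff(names(group_map), samples)
  if (length(unknown))
    stop("unknown sample(s) in group_map: ", paste(unknown, collapse = ", "))
  missing <- setdiff(samples, names(group_map))
  if (length(missing))
    stop("sample(s) without group label: ", paste(missing, collapse = ", "))
  message(sprintf("read %d features x %d samples from %s",
                  nrow(vals), ncol(vals), path))
  expression_matrix(vals, group_map, pairs = pair_map, kind = feature_kind)
}

# Collapse rows of 'vals' sharing the same id in 'ids' under a policy.
collapse_duplicate_rows <- function(vals, ids, policy) {
  if (!anyDuplicated(ids)) {
    rownames(vals) <- ids
    return(vals)
  }
  n_dup <- sum(duplicated(ids))
  keep <- vapply(split(seq_along(ids), ids), function(rows) rows[1], 1L)
  out <- matrix(NA_real_, length(keep), ncol(vals),
                dimnames = list(names(keep), colnames(vals)))
  for (id in names(keep)) {
    rows <- which(ids == id)
    if (length(rows) == 1L) {
      out[id, ] <- vals[rows, ]
    } else if (policy == "max_mean") {
      best <- rows[which.max(rowMeans(vals[rows, , drop = FALSE], na.rm = TRUE))]
      out[id, ] <- vals[best, ]
    } else {
      out[id, ] <- colMeans(vals[rows, , drop = FALSE], na.rm = TRUE)
    }
  }
  # restore first-occurrence ordering
  out <- out[unique(ids), , drop = FALSE]
  message(sprintf("collapsed %d duplicate feature row(s) (policy %s)",
                  n_dup, policy))
  out
}

#' Write an expression matrix to TSV
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip reproduces them exactly.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_table <- function(em, path) {
  vals <- em$values
  chr <- apply(vals, 2, function(col)
    ifelse(is.na(col), "NA", formatC(col, digits = 17, format = "g")))
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(vals))
  out <- cbind(feature_id = rownames(vals), as.data.frame(chr))
  colnames(out) <- c("feature_id", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a sample sheet (sample_id, group, optional pair_id)
#' @param em An [expression_matrix()].
#' @param path TSV path.
#' @export
write_sample_sheet <- function(em, path) {
  df <- data.frame(sample_id = names(em$groups), group = unname(em$groups),
                   stringsAsFactors = FALSE)
  if (!is.null(em$pairs)) df$pair_id <- unname(em$pairs[df$sample_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @return `read_sample_sheet()`: a list with `groups` (named character) and
#'   `pairs` (named character or `NULL`).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("sample sheet needs columns sample_id, group")
  groups <- stats::setNames(df$group, df$sample_id)
  pairs <- if ("pair_id" %in% colnames(df))
    stats::setNames(df$pair_id, df$sample_id) else NULL
  list(groups = groups, pairs = pairs)
}

#' Log2-transform an expression matrix
#'
#' @param em An [expression_matrix()].
#' @param offset Non-negative pseudo-count added before taking log2 (default
#'   1, so zero maps to zero).
#' @param already_log If `TRUE` the matrix is assumed to be on the log2 scale
#'   already and is returned unchanged (the transform is a no-op, making the
#'   operation idempotent).
#' @return The transformed [expression_matrix()].
#' @export
log2_transform <- function(em, offset = 1, already_log = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (already_log) return(em)
  if (offset < 0) stop("'offset' must be non-negative")
  if (any(em$values < 0, na.rm = TRUE))
    stop("negative values: data already log-scale? set already_log = TRUE")
  v <- log2(em$values + offset)
  if (any(is.infinite(v)))
    stop("log2 transform produced non-finite values; use a positive offset")
  em$values <- v
  em
}

#' Map probe identifiers to canonical feature ids
#'
#' Converts probe names to canonical identifiers (circBase ids, miRBase ids or
#' gene symbols). Unmapped probes are dropped (and counted in a message);
#' probes mapping to the same canonical id are collapsed.
#'
#' @param em An [expression_matrix()].
#' @param mapping Named character vector: `names` are probe ids, values the
#'   canonical ids.
#' @inheritParams read_expression_table
#' @return The re-identified [expression_matrix()]; never has more features
#'   than the input.
#' @export
map_feature_ids <- function(em, mapping, collapse = c("max_mean", "mean")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  collapse <- match.arg(collapse)
  if (length(mapping) == 0) stop("empty id mapping")
  if (is.null(names(mapping))) stop("'mapping' must be named by probe id")
  keep <- rownames(em$values) %in% names(mapping)
  n_drop <- sum(!keep)
  if (!any(keep)) stop("no features covered by the mapping")
  vals <- em$values[keep, , drop = FALSE]
  new_ids <- unname(mapping[rownames(vals)])
  rownames(vals) <- make.unique(new_ids)
  vals <- collapse_duplicate_rows(vals, new_ids, collapse)
  message(sprintf("mapped %d features (%d unmapped probes dropped)",
                  nrow(vals), n_drop))
  expression_matrix(vals, em$groups, em$pairs, em$kind)
}

#' Read a miRNA interaction table
#'
#' Two-column TSV with header `mirna_id<TAB>partner_id`, one interaction pair
#' per line (the format of ENCORI/starBase pair exports). Duplicate pairs are
#' removed.
#'
#' @param path TSV path.
#' @param kind `"miRNA_circRNA"` or `"miRNA_mRNA"`.
#' @return An `InteractionTable`: list with `kind` and `pairs`
#'   (a data frame with columns `mirna_id`, `partner_id`).
#' @export
read_interaction_table <- function(path, kind = c("miRNA_circRNA", "miRNA_mRNA")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!identical(colnames(df)[1:2], c("mirna_id", "partner_id")))
    stop("interaction table must have header 'mirna_id\\tpartner_id'")
  interaction_table(df$mirna_id, df$partner_id, kind)
}

#' @rdname read_interaction_table
#' @param mirna_id,partner_id Character vectors of equal length.
#' @export
interaction_table <- function(mirna_id, partner_id,
                              kind = c("miRNA_circRNA", "miRNA_mRNA")) {
  kind <- match.arg(kind)
  mirna_id <- as.character(mirna_id)
  partner_id <- as.character(partner_id)
  if (length(mirna_id) != length(partner_id))
    stop("id vectors must have equal length")
  if (any(!nzchar(mirna_id)) || any(!nzchar(partner_id)))
    stop("empty interaction identifier")
  df <- unique(data.frame(mirna_id = mirna_id, partner_id = partner_id,
                          stringsAsFactors = FALSE))
  n_dup <- length(mirna_id) - nrow(df)
  if (n_dup > 0) message(sprintf("removed %d duplicate pair(s)", n_dup))
  rownames(df) <- NULL
  structure(list(kind = kind, pairs = df), class = "InteractionTable")
}

#' @export
print.InteractionTable <- function(x, ...) {
  cat(sprintf("InteractionTable [%s]: %d pairs (%d miRNAs, %d partners)\n",
              x$kind, nrow(x$pairs), length(unique(x$pairs$mirna_id)),
              length(unique(x$pairs$partner_id))))
  invisible(x)
}

#' @rdname read_interaction_table
#' @param tab An `InteractionTable`.
#' @export
write_interaction_table <- function(tab, path) {
  utils::write.table(tab$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT format: one set per line, `name<TAB>description<TAB>gene...`.
#' Gene symbols are uppercased on ingest so that expression tables and gene
#' sets cannot disagree by case.
#'
#' @param path GMT path.
#' @return A `GeneSetCollection`: named list of character vectors, with
#'   per-set descriptions in `attr(, "descriptions")`.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("malformed GMT line %d: expected >=3 tab-separated fields", i))
    nm <- fields[1]
    if (nm %in% names(sets))
      stop(sprintf("duplicate gene-set name '%s' at line %d", nm, i))
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("gene set '%s' (line %d) has no members", nm, i))
    sets[[nm]] <- genes
    desc[nm] <- fields[2]
  }
  structure(sets, descriptions = desc, class = c("GeneSetCollection", "list"))
}

#' @rdname read_gene_sets_gmt
#' @param sets Named list of character vectors.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical overall-survival table
#'
#' TSV with columns `sample_id`, `os_time_days` (non-negative), `os_event`
#' (1 = death observed, 0 = censored).
#'
#' @param path TSV path.
#' @return Data frame with columns `sample_id`, `os_time`, `os_event`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("sample_id", "os_time_days", "os_event")
  if (!all(need %in% colnames(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate clinical sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  os_time <- suppressWarnings(as.numeric(df$os_time_days))
  os_event <- suppressWarnings(as.numeric(df$os_event))
  if (any(is.na(os_time)) || any(os_time < 0))
    stop("os_time_days must be numeric and >= 0")
  if (any(is.na(os_event)) || !all(os_event %in% c(0, 1)))
    stop("os_event must be 0 (censored) or 1 (death)")
  data.frame(sample_id = df$sample_id, os_time = os_time, os_event = os_event,
             stringsAsFactors = FALSE)
}

#' @rdname read_clinical_table
#' @param clinical Data frame as returned by `read_clinical_table()`.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- data.frame(sample_id = clinical$sample_id,
                    os_time_days = clinical$os_time,
                    os_event = clinical$os_event)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-response (IC50) matrix
#'
#' TSV with cell lines in rows and drugs in columns, preceded by a mandatory
#' metadata line `#scale=ln_ic50` or `#scale=log10_ic50` declaring the IC50
#' log scale (the GDSC convention is natural-log IC50). Missing entries are
#' allowed and kept as `NA`.
#'
#' @param path TSV path.
#' @return A `DrugResponseMatrix`: list with `ic50` (cell line x drug numeric
#'   matrix) and `scale`.
#' @export
read_drug_matrix <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#scale=(ln_ic50|log10_ic50)$", first))[[1]]
  if (length(m) != 2)
    stop("drug matrix must start with '#scale=ln_ic50' or '#scale=log10_ic50'")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 1,
                          check.names = FALSE)
  ic50 <- as.matrix(df[, -1, drop = FALSE])
  rownames(ic50) <- df[[1]]
  if (!is.numeric(ic50)) stop("non-numeric IC50 values")
  drug_response_matrix(ic50, m[2])
}

#' @rdname read_drug_matrix
#' @param ic50 Numeric matrix, cell lines x drugs.
#' @param scale `"ln_ic50"` or `"log10_ic50"`.
#' @export
drug_response_matrix <- function(ic50, scale = c("ln_ic50", "log10_ic50")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(ic50), is.numeric(ic50))
  if (is.null(rownames(ic50)) || is.null(colnames(ic50)))
    stop("ic50 matrix needs cell-line rownames and drug colnames")
  structure(list(ic50 = ic50, scale = scale), class = "DrugResponseMatrix")
}

#' @rdname read_drug_matrix
#' @param drugs A `DrugResponseMatrix`.
#' @export
write_drug_matrix <- function(drugs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#scale=", drugs$scale), con)
  out <- cbind(cell_line = rownames(drugs$ic50), as.data.frame(drugs$ic50))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
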