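#' Build a pipeline configuration
#'
#' Collects the input paths, thresholds and output directory driving
#' [run_pipeline()]. Configurations can also be written as YAML and read
#' back with [read_pipeline_config()]; [validate_pipeline_config()] checks
#' paths and threshold ranges before any stage runs.
#'
#' @param inputs Named list of input paths: cohort entries `circ_a`,
#'   `circ_b`, `mirna`, `mrna` (each a list with `expr` and `samples` TSV
#'   paths), plus `mc_pairs`, `mg_pairs`, `gene_sets`, `clinical`,
#'   `cell_line_expr`, `drug_ic50`.
#' @param output_dir Directory for stage outputs and the run report.
#' @param thresholds A [threshold_config()].
#' @param network_mode `"sign_rule"` or `"correlation"`.
#' @param enrichment_p,survival_p Strict p-value cutoffs for the enrichment
#'   and survival stages.
#' @param drug_fdr Strict FDR cutoff for the drug screen.
#' @param seed Echoed into the report for provenance; the analysis stages
#'   themselves are deterministic and draw no random numbers.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(inputs, output_dir,
                            thresholds = threshold_config(),
                            network_mode = c("sign_rule", "correlation"),
                            enrichment_p = 0.05, survival_p = 0.05,
                            drug_fdr = 0.05, seed = NULL) {
  network_mode <- match.arg(network_mode)
  structure(list(inputs = inputs, output_dir = output_dir,
                 thresholds = thresholds, network_mode = network_mode,
                 enrichment_p = enrichment_p, survival_p = survival_p,
                 drug_fdr = drug_fdr, seed = seed),
            class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param path YAML configuration path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$thresholds
  if (is.null(th)) th <- list()
  thresholds <- threshold_config(
    p_threshold = th$p_threshold %||% 0.05,
    fc_threshold = th$fc_threshold %||% 1,
    use_adjusted_p = isTRUE(th$use_adjusted_p),
    de_method = th$de_method %||% "auto")
  pipeline_config(inputs = y$inputs, output_dir = y$output_dir,
                  thresholds = thresholds,
                  network_mode = y$network_mode %||% "sign_rule",
                  enrichment_p = y$enrichment_p %||% 0.05,
                  survival_p = y$survival_p %||% 0.05,
                  drug_fdr = y$drug_fdr %||% 0.05,
                  seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname pipeline_config
#' @param config A `PipelineConfig`.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c("enrichment_p", "survival_p", "drug_fdr")) {
    v <- config[[p]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("invalid configuration: ", p, " must lie in (0, 1)")
  }
  th <- config$thresholds
  if (th$p_threshold <= 0 || th$p_threshold >= 1)
    stop("invalid configuration: p_threshold must lie in (0, 1)")
  ins <- config$inputs
  need_cohorts <- c("circ_a", "circ_b", "mirna", "mrna")
  need_files <- c("mc_pairs", "mg_pairs", "gene_sets", "clinical",
                  "cell_line_expr", "drug_ic50")
  missing <- setdiff(c(need_cohorts, need_files), names(ins))
  if (length(missing))
    stop("invalid configuration: missing inputs: ",
         paste(missing, collapse = ", "))
  paths <- c(unlist(lapply(ins[need_cohorts], function(x)
    c(x$expr, x$samples))), unlist(ins[need_files]))
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("invalid configuration: missing file(s): ",
         paste(absent, collapse = ", "))
  invisible(config)
}

read_cohort <- function(entry, kind) {
  sheet <- read_sample_sheet(entry$samples)
  read_expression_table(entry$expr, kind, sheet$groups, sheet$pairs)
}

#' Run the full ceRNA discovery pipeline
#'
#' Executes the stages in order: per-cohort differential expression; Fisher
#' overlap of the two circRNA DE lists (the circRNAs carried forward are
#' those differential in both cohorts with the same direction); sign-rule
#' ceRNA network assembly; hypergeometric enrichment of the genes of the
#' circRNA with the largest target set; median-split log-rank screening of
#' all network genes; and the Spearman drug-IC50 screen of the prognostic
#' hits. All stage tables are written as TSV under `output_dir`, together
#' with a machine-readable `report.json` and a human-readable `report.txt`.
#' A rerun on identical inputs is byte-identical: the analysis stages use no
#' random numbers.
#'
#' @param config A `PipelineConfig` or the path to a YAML configuration.
#' @return The run report, invisibly: a list of per-stage counts, the
#'   thresholds used and the package version.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- stage: input -----------------------------------------------------
  ins <- config$inputs
  circ_a <- stage("input", read_cohort(ins$circ_a, "circRNA"))
  circ_b <- stage("input", read_cohort(ins$circ_b, "circRNA"))
  mirna <- stage("input", read_cohort(ins$mirna, "miRNA"))
  mrna <- stage("input", read_cohort(ins$mrna, "mRNA"))
  mc_pairs <- stage("input", read_interaction_table(ins$mc_pairs, "miRNA_circRNA"))
  mg_pairs <- stage("input", read_interaction_table(ins$mg_pairs, "miRNA_mRNA"))
  gene_sets <- stage("input", read_gene_sets_gmt(ins$gene_sets))
  clinical <- stage("input", read_clinical_table(ins$clinical))
  cell_expr <- stage("input", {
    tab <- utils::read.delim(ins$cell_line_expr, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m
  })
  drugs <- stage("input", read_drug_matrix(ins$drug_ic50))

  # --- stage: differential expression -----------------------------------
  de <- stage("de", list(
    circ_a = differential_expression(circ_a, th, "circ_a"),
    circ_b = differential_expression(circ_b, th, "circ_b"),
    mirna = differential_expression(mirna, th, "mirna"),
    mrna = differential_expression(mrna, th, "mrna")))
  for (nm in names(de))
    write_de_table(de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))

  # --- stage: circRNA overlap -------------------------------------------
  overlap <- stage("overlap", {
    universe <- intersect(rownames(circ_a$values), rownames(circ_b$values))
    a_ids <- intersect(names(de_direction_map(de$circ_a)), universe)
    b_ids <- intersect(names(de_direction_map(de$circ_b)), universe)
    ov <- overlap_significance(a_ids, b_ids, universe)
    dir_a <- de_direction_map(de$circ_a)
    dir_b <- de_direction_map(de$circ_b)
    shared <- intersect(a_ids, b_ids)
    concordant <- shared[dir_a[shared] == dir_b[shared]]
    list(test = ov, circ_ids = sort(concordant),
         directions = dir_a[sort(concordant)])
  })
  circ_de_overlap <- data.frame(feature_id = overlap$circ_ids,
                                direction = unname(overlap$directions),
                                stringsAsFactors = FALSE)
  utils::write.table(circ_de_overlap,
                     file.path(out_dir, "circ_overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- stage: ceRNA network ---------------------------------------------
  net <- stage("network", build_cerna_network(
    circ_de_overlap, de$mirna, de$mrna, mc_pairs, mg_pairs,
    mode = config$network_mode,
    expr_mirna = if (config$network_mode == "correlation") mirna else NULL,
    expr_circ = if (config$network_mode == "correlation") circ_a else NULL,
    expr_gene = if (config$network_mode == "correlation") mrna else NULL))
  write_cerna_network(net, file.path(out_dir, "cerna_network.tsv"))
  de_counts <- c(circRNA = max(1L, nrow(circ_de_overlap)),
                 miRNA = max(1L, length(de_direction_map(de$mirna))),
                 mRNA = max(1L, length(de_direction_map(de$mrna))))
  summ <- network_summary(net, de_counts)
  utils::write.table(summ$composition,
                     file.path(out_dir, "network_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$per_circ,
                     file.path(out_dir, "network_per_circ.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: enrichment -------------------------------------------------
  enr <- stage("enrich", {
    if (nrow(summ$per_circ)) {
      top_circ <- summ$per_circ$circ_id[1]
      sub <- suppressWarnings(subnetwork_by_circ(net, top_circ))
      query <- unique(sub$triplets$gene_id)
      res <- hypergeometric_enrichment(query, gene_sets,
                                       rownames(mrna$values))
      list(circ_id = top_circ, results = res,
           top = top_terms(res, 10, config$enrichment_p))
    } else {
      list(circ_id = NA_character_,
           results = data.frame(), top = data.frame())
    }
  })
  if (nrow(enr$results))
    utils::write.table(enr$results, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: survival screen -------------------------------------------
  screen <- stage("survive", {
    genes <- unique(net$triplets$gene_id)
    if (length(genes))
      prognostic_screen(mrna, clinical, genes, config$survival_p)
    else
      data.frame(gene_id = character(), n_high = integer(),
                 n_low = integer(), chi_square = numeric(),
                 p_value = numeric(), significant = logical(),
                 skip_reason = character())
  })
  write_survival_screen(screen, file.path(out_dir, "survival_screen.tsv"))
  prognostic_hits <- screen$gene_id[which(screen$significant)]

  # --- stage: drug screen ------------------------------------------------
  drug <- stage("drugscreen", {
    if (length(prognostic_hits))
      drug_gene_screen(cell_expr, drugs, prognostic_hits, config$drug_fdr)
    else
      data.frame(gene_id = character(), drug_id = character(),
                 n = integer(), rho = numeric(), p_value = numeric(),
                 fdr = numeric(), direction = character(),
                 flagged = logical(), skip_reason = character())
  })
  write_drug_screen(drug, file.path(out_dir, "drug_screen.tsv"))

  # --- report -------------------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("ceRNAscreen")),
    seed = config$seed,
    thresholds = unclass(th),
    network_mode = config$network_mode,
    de = lapply(de, function(d) {
      dirs <- table(factor(d$direction, c("up", "down", "none")))
      list(n_features = nrow(d), n_up = unname(dirs[["up"]]),
           n_down = unname(dirs[["down"]]))
    }),
    overlap = list(n_overlap = overlap$test$n_overlap,
                   n_universe = overlap$test$n_universe,
                   p_value = overlap$test$p_value,
                   odds_ratio = overlap$test$odds_ratio,
                   n_concordant = nrow(circ_de_overlap)),
    network = list(n_triplets = nrow(net$triplets),
                   composition = summ$composition,
                   per_circ = summ$per_circ),
    enrichment = list(circ_id = enr$circ_id,
                      n_tested = nrow(enr$results),
                      n_top = nrow(enr$top),
                      top_sets = enr$top$set_name),
    survival = list(n_screened = nrow(screen),
                    n_significant = length(prognostic_hits),
                    hits = prognostic_hits),
    drug = list(n_pairs_tested = sum(is.na(drug$skip_reason)),
                n_flagged = sum(drug$flagged),
                flagged = drug[drug$flagged, c("gene_id", "drug_id")]))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

format_report <- function(r) {
  c(sprintf("ceRNAscreen %s pipeline report", r$package_version),
    sprintf("thresholds: p < %g, |log2FC| > %g, method %s%s",
            r$thresholds$p_threshold, r$thresholds$fc_threshold,
            r$thresholds$de_method,
            if (isTRUE(r$thresholds$use_adjusted_p)) " (BH-adjusted p)" else ""),
    sprintf("network mode: %s", r$network_mode),
    "",
    vapply(names(r$de), function(nm)
      sprintf("DE [%s]: %d features, %d up / %d down", nm,
              r$de[[nm]]$n_features, r$de[[nm]]$n_up, r$de[[nm]]$n_down), ""),
    sprintf("circRNA overlap: %d shared (universe %d), Fisher p = %.3g, %d concordant carried forward",
            r$overlap$n_overlap, r$overlap$n_universe, r$overlap$p_value,
            r$overlap$n_concordant),
    sprintf("ceRNA network: %d triplets", r$network$n_triplets),
    sprintf("enrichment (top circRNA %s): %d sets tested, %d significant",
            r$enrichment$circ_id, r$enrichment$n_tested, r$enrichment$n_top),
    sprintf("survival screen: %d genes, %d prognostic", r$survival$n_screened,
            r$survival$n_significant),
    sprintf("drug screen: %d pairs tested, %d flagged", r$drug$n_pairs_tested,
            r$drug$n_flagged))
}

#' Write a synthetic study together with a ready-to-run pipeline config
#'
#' Convenience wrapper used by the `simulate` entry point: generates a
#' synthetic study, writes its files under `dir` and drops a
#' `pipeline_config.yaml` pointing at them, so `run_pipeline()` (or the
#' `run-all` command) can consume the directory directly.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param config Optional [synthetic_config()]; defaults to
#'   `synthetic_config(seed)`.
#' @return Path of the written YAML config, invisibly.
#' @export
simulate_study_dir <- function(seed, dir, config = NULL) {
  if (is.null(config)) config <- synthetic_config(seed)
  study <- generate_synthetic_study(config)
  write_synthetic_study(study, dir)
  p <- function(...) file.path(dir, ...)
  cfg <- list(
    seed = as.integer(seed),
    output_dir = p("results"),
    thresholds = list(p_threshold = 0.05, fc_threshold = 1,
                      use_adjusted_p = FALSE, de_method = "auto"),
    network_mode = "sign_rule",
    enrichment_p = 0.05, survival_p = 0.05, drug_fdr = 0.05,
    inputs = list(
      circ_a = list(expr = p("circ_a_expr.tsv"), samples = p("circ_a_samples.tsv")),
      circ_b = list(expr = p("circ_b_expr.tsv"), samples = p("circ_b_samples.tsv")),
      mirna = list(expr = p("mirna_seq_expr.tsv"), samples = p("mirna_seq_samples.tsv")),
      mrna = list(expr = p("mrna_seq_expr.tsv"), samples = p("mrna_seq_samples.tsv")),
      mc_pairs = p("mirna_circ_pairs.tsv"),
      mg_pairs = p("mirna_gene_pairs.tsv"),
      gene_sets = p("gene_sets.gmt"),
      clinical = p("clinical.tsv"),
      cell_line_expr = p("cell_line_expr.tsv"),
      drug_ic50 = p("drug_ic50.tsv")))
  yaml::write_yaml(cfg, p("pipeline_config.yaml"))
  invisible(p("pipeline_config.yaml"))
}
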