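#' Configuration for the synthetic study generator
#'
#' Defines a complete synthetic ceRNA study: expression cohorts whose shapes
#' mirror the typical discovery design (two small paired circRNA microarray
#' cohorts, one small paired mRNA array cohort, and large unpaired
#' miRNA/mRNA sequencing cohorts with 45 normal and 450 tumor samples),
#' planted differential expression, planted sign-rule-satisfying ceRNA
#' triplets with per-condition decoys, planted prognostic genes and planted
#' drug-gene associations. Every random draw is governed by `seed`.
#'
#' @param seed Integer seed; mandatory, all outputs are a pure function of it
#'   and the configuration.
#' @param n_features Named vector: number of features per kind.
#' @param cohorts Named list of cohort shapes. Paired cohorts use
#'   `pairs = k` (k tumor/normal pairs); unpaired cohorts use
#'   `normal = n, tumor = m`. Each entry also carries `kind`.
#' @param de_fraction Fraction of features per kind with planted differential
#'   expression (half up, half down).
#' @param effect_size Planted |log2 shift| in tumor samples (default 2).
#' @param within_sd Gaussian noise standard deviation on the log2 scale
#'   (default 0.5).
#' @param patient_sd Standard deviation of the shared patient baseline in
#'   paired cohorts (default 0.25); removed by the paired test, inflating
#'   variance slightly for unpaired analysis, as in real paired designs.
#' @param baseline_range Range of per-feature baseline log2 abundance.
#' @param n_triplets Number of planted circRNA-miRNA backbones.
#' @param genes_per_triplet Target genes per backbone.
#' @param decoys_per_type Decoy triplets per violation type (five types: a
#'   non-DE circRNA, miRNA or gene, and the two sign-rule breaches).
#' @param n_background_pairs Random interaction pairs among non-DE features
#'   added to each table as inert background.
#' @param n_prognostic Number of planted prognostic genes (taken from the
#'   planted network genes).
#' @param hazard_ratio True hazard ratio between high and low expression
#'   groups of each planted prognostic gene (default 3).
#' @param censoring_rate Target fraction of censored samples (default 0.6,
#'   i.e. ~40% observed events).
#' @param baseline_hazard Baseline exponential hazard per day (default
#'   1/1000, a median survival around two years).
#' @param n_cell_lines,n_drugs Shape of the drug-response screen.
#' @param n_drug_pairs Planted monotone gene-drug relations.
#' @param drug_effect Signal-to-noise ratio |b|/sd(noise) of the planted
#'   linear IC50 dependence (default 1).
#' @param drug_effect_sign Sign of the planted slope (-1 = sensitizing).
#' @param drug_missing_rate Fraction of missing IC50 entries.
#' @param n_gene_sets Number of random gene sets in the generated GMT (one
#'   additional set collects the planted network genes).
#' @param gene_set_size Genes per set.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed,
                             n_features = c(circRNA = 200L, miRNA = 150L,
                                            mRNA = 400L),
                             cohorts = list(
                               circ_a = list(kind = "circRNA", pairs = 4L),
                               circ_b = list(kind = "circRNA", pairs = 5L),
                               mrna_array = list(kind = "mRNA", pairs = 6L),
                               mrna_seq = list(kind = "mRNA", normal = 45L,
                                               tumor = 450L),
                               mirna_seq = list(kind = "miRNA", normal = 45L,
                                                tumor = 450L)),
                             de_fraction = 0.1, effect_size = 2,
                             within_sd = 0.5, patient_sd = 0.25,
                             baseline_range = c(4, 12),
                             n_triplets = 3L, genes_per_triplet = 2L,
                             decoys_per_type = 2L, n_background_pairs = 30L,
                             n_prognostic = 1L, hazard_ratio = 3,
                             censoring_rate = 0.6, baseline_hazard = 1 / 1000,
                             n_cell_lines = 30L, n_drugs = 10L,
                             n_drug_pairs = 1L, drug_effect = 1,
                             drug_effect_sign = -1, drug_missing_rate = 0.1,
                             n_gene_sets = 10L, gene_set_size = 25L) {
  if (missing(seed) || is.na(seed)) stop("'seed' is mandatory")
  if (any(n_features <= 0) || n_triplets < 0 || n_cell_lines <= 0)
    stop("counts must be positive")
  if (de_fraction > 0 && effect_size <= 0)
    stop("planted DE requires a positive effect size")
  if (hazard_ratio <= 0) stop("hazard ratio must be > 0")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  cfg <- as.list(environment())
  structure(cfg, class = "SyntheticConfig")
}

# Deterministic per-output substream seed (kept below 2^31) so adding one
# generator does not perturb the draws of another.
substream_seed <- function(seed, name) {
  streams <- c(expression = 1L, interactions = 2L, gene_sets = 3L,
               clinical = 4L, drugs = 5L)
  off <- streams[[name]]
  as.integer((as.numeric(seed) * 31L + off * 7919) %% 2147483629)
}

synthetic_feature_ids <- function(n_features) {
  list(circRNA = sprintf("circ_s%04d", seq_len(n_features[["circRNA"]])),
       miRNA = sprintf("miR-s%03d", seq_len(n_features[["miRNA"]])),
       mRNA = sprintf("GS%04d", seq_len(n_features[["mRNA"]])))
}

#' Generate expression cohorts with planted differential expression
#'
#' Per-feature baseline log2 abundance is drawn uniformly over
#' `baseline_range`; samples get Gaussian noise at `within_sd`; paired
#' cohorts additionally share a per-patient baseline shift. Planted features
#' are shifted by `+/- effect_size` in tumor samples, with the same feature
#' set and directions in every cohort of the same kind.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohorts` (named list of [expression_matrix()]) and
#'   `de` (data frame `kind`, `feature_id`, `direction`: the planted truth).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(substream_seed(config$seed, "expression"))
  ids <- synthetic_feature_ids(config$n_features)

  de <- do.call(rbind, lapply(names(ids), function(kind) {
    n <- length(ids[[kind]])
    n_de <- round(config$de_fraction * n)
    if (n_de == 0)
      return(data.frame(kind = character(), feature_id = character(),
                        direction = character(), stringsAsFactors = FALSE))
    planted <- sample(ids[[kind]], n_de)
    dirs <- rep(c("up", "down"), length.out = n_de)
    data.frame(kind = kind, feature_id = planted, direction = dirs,
               stringsAsFactors = FALSE)
  }))

  shift <- function(kind) {
    s <- stats::setNames(rep(0, length(ids[[kind]])), ids[[kind]])
    d <- de[de$kind == kind, ]
    s[d$feature_id] <- ifelse(d$direction == "up", 1, -1) * config$effect_size
    s
  }

  cohorts <- lapply(names(config$cohorts), function(nm) {
    spec <- config$cohorts[[nm]]
    kind <- spec$kind
    feats <- ids[[kind]]
    baseline <- stats::runif(length(feats), config$baseline_range[1],
                             config$baseline_range[2])
    sh <- shift(kind)
    if (!is.null(spec$pairs)) {
      k <- spec$pairs
      tumor <- sprintf("%s_T%02d", nm, seq_len(k))
      normal <- sprintf("%s_N%02d", nm, seq_len(k))
      samples <- c(tumor, normal)
      groups <- stats::setNames(rep(c("tumor", "normal"), each = k), samples)
      pairs <- stats::setNames(rep(sprintf("%s_P%02d", nm, seq_len(k)), 2),
                               samples)
      pat_eff <- matrix(stats::rnorm(length(feats) * k, 0, config$patient_sd),
                        length(feats), k)
      vals <- baseline +
        cbind(pat_eff, pat_eff) +
        matrix(stats::rnorm(length(feats) * 2 * k, 0, config$within_sd),
               length(feats), 2 * k)
      vals[, seq_len(k)] <- vals[, seq_len(k)] + sh
      dimnames(vals) <- list(feats, samples)
      expression_matrix(vals, groups, pairs, kind)
    } else {
      tumor <- sprintf("%s_T%03d", nm, seq_len(spec$tumor))
      normal <- sprintf("%s_N%03d", nm, seq_len(spec$normal))
      samples <- c(tumor, normal)
      groups <- stats::setNames(rep(c("tumor", "normal"),
                                    c(spec$tumor, spec$normal)), samples)
      vals <- baseline +
        matrix(stats::rnorm(length(feats) * length(samples), 0,
                            config$within_sd),
               length(feats), length(samples))
      vals[, seq_len(spec$tumor)] <- vals[, seq_len(spec$tumor)] + sh
      dimnames(vals) <- list(feats, samples)
      expression_matrix(vals, groups, NULL, kind)
    }
  })
  names(cohorts) <- names(config$cohorts)
  list(cohorts = cohorts, de = de)
}

#' Generate interaction tables realizing planted triplets plus decoys
#'
#' Emits the miRNA-circRNA and miRNA-mRNA pairs wiring each planted triplet,
#' plus decoy wirings that each violate exactly one network condition (a
#' non-DE circRNA, miRNA or gene, or one of the two sign-rule breaches:
#' gene moving with the miRNA, or gene moving against the circRNA), plus
#' inert background pairs among non-DE features. Each decoy uses a dedicated
#' miRNA so it forms exactly one candidate triplet, making the per-decoy
#' audit unambiguous.
#'
#' @param config A [synthetic_config()].
#' @param de Planted-DE data frame from [generate_expression()].
#' @return List with `mc_pairs`, `mg_pairs` (`InteractionTable`s),
#'   `triplets` (planted truth) and `decoys` (each with its violation type).
#' @export
generate_interactions <- function(config, de) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(substream_seed(config$seed, "interactions"))
  ids <- synthetic_feature_ids(config$n_features)

  pool <- function(kind, dir = NULL, de_status = TRUE) {
    if (!de_status)
      return(setdiff(ids[[kind]], de$feature_id[de$kind == kind]))
    sel <- de$kind == kind
    if (!is.null(dir)) sel <- sel & de$direction == dir
    de$feature_id[sel]
  }
  used <- character()
  take <- function(kind, dir = NULL, de_status = TRUE, n = 1L) {
    avail <- setdiff(pool(kind, dir, de_status), used)
    if (length(avail) < n)
      stop("not enough ", if (de_status) "DE " else "non-DE ", kind,
           " features to plant the requested network structure")
    got <- avail[seq_len(n)]
    used <<- c(used, got)
    got
  }
  flip <- function(d) ifelse(d == "up", "down", "up")

  mc <- list(); mg <- list()
  add_mc <- function(m, c) mc[[length(mc) + 1L]] <<- c(m, c)
  add_mg <- function(m, g) mg[[length(mg) + 1L]] <<- c(m, g)

  triplets <- list()
  for (i in seq_len(config$n_triplets)) {
    d <- if (i %% 2 == 1) "down" else "up"
    circ <- take("circRNA", d)
    mirna <- take("miRNA", flip(d))
    genes <- take("mRNA", d, n = config$genes_per_triplet)
    add_mc(mirna, circ)
    for (g in genes) {
      add_mg(mirna, g)
      triplets[[length(triplets) + 1L]] <-
        data.frame(circ_id = circ, mirna_id = mirna, gene_id = g,
                   circ_direction = d, mirna_direction = flip(d),
                   gene_direction = d, stringsAsFactors = FALSE)
    }
  }
  triplets <- if (length(triplets)) do.call(rbind, triplets) else
    empty_triplets()

  decoys <- list()
  add_decoy <- function(type, circ, mirna, gene) {
    add_mc(mirna, circ)
    add_mg(mirna, gene)
    decoys[[length(decoys) + 1L]] <<-
      data.frame(type = type, circ_id = circ, mirna_id = mirna,
                 gene_id = gene, stringsAsFactors = FALSE)
  }
  for (r in seq_len(config$decoys_per_type)) {
    d <- if (r %% 2 == 1) "up" else "down"
    # circRNA not differentially expressed
    add_decoy("non_de_circ", take("circRNA", de_status = FALSE),
              take("miRNA", flip(d)), take("mRNA", d))
    # miRNA not differentially expressed
    add_decoy("non_de_mirna", take("circRNA", d),
              take("miRNA", de_status = FALSE), take("mRNA", d))
    # gene not differentially expressed
    add_decoy("non_de_gene", take("circRNA", d), take("miRNA", flip(d)),
              take("mRNA", de_status = FALSE))
    # sign breach: gene moves with the miRNA (and with the circRNA)
    add_decoy("sign_breach_mirna", take("circRNA", d), take("miRNA", d),
              take("mRNA", d))
    # sign breach: gene moves against the circRNA (but against the miRNA too)
    add_decoy("sign_breach_circ", take("circRNA", d), take("miRNA", d),
              take("mRNA", flip(d)))
  }
  decoys <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(type = character(), circ_id = character(),
               mirna_id = character(), gene_id = character())

  # inert background pairs among non-DE features only
  bg_m <- setdiff(pool("miRNA", de_status = FALSE), used)
  bg_c <- setdiff(pool("circRNA", de_status = FALSE), used)
  bg_g <- setdiff(pool("mRNA", de_status = FALSE), used)
  nb <- config$n_background_pairs
  if (nb > 0 && length(bg_m) && length(bg_c) && length(bg_g)) {
    for (i in seq_len(nb)) add_mc(sample(bg_m, 1), sample(bg_c, 1))
    for (i in seq_len(nb)) add_mg(sample(bg_m, 1), sample(bg_g, 1))
  }

  mc <- do.call(rbind, mc)
  mg <- do.call(rbind, mg)
  list(mc_pairs = interaction_table(mc[, 1], mc[, 2], "miRNA_circRNA"),
       mg_pairs = interaction_table(mg[, 1], mg[, 2], "miRNA_mRNA"),
       triplets = cerna_network(triplets)$triplets,
       decoys = decoys)
}

#' Generate a gene-set collection containing the planted network genes
#'
#' Random gene sets drawn from all mRNA features, plus one set
#' (`SET_SYNTH_PLANTED`) holding the planted network genes padded with random
#' genes, so over-representation of the recovered network gene list can be
#' checked against a known enriched set.
#'
#' @param config A [synthetic_config()].
#' @param triplets Planted triplet data frame from [generate_interactions()].
#' @return A `GeneSetCollection`.
#' @export
generate_gene_sets <- function(config, triplets) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(substream_seed(config$seed, "gene_sets"))
  genes <- synthetic_feature_ids(config$n_features)$mRNA
  sets <- lapply(seq_len(config$n_gene_sets), function(i)
    sort(sample(genes, min(config$gene_set_size, length(genes)))))
  names(sets) <- sprintf("SET_SYNTH_%02d", seq_along(sets))
  planted <- unique(triplets$gene_id)
  pad <- sample(setdiff(genes, planted),
                max(0, config$gene_set_size - length(planted)))
  sets$SET_SYNTH_PLANTED <- sort(c(planted, pad))
  structure(sets,
            descriptions = stats::setNames(
              c(rep("random synthetic set", config$n_gene_sets),
                "planted network genes"), names(sets)),
            class = c("GeneSetCollection", "list"))
}

#' Generate overall-survival data with planted prognostic genes
#'
#' Survival times are exponential with hazard
#' `h0 * exp(log(HR) * z_g)` per planted gene, where `z_g` indicates tumor
#' samples whose expression of that gene lies strictly above the cohort
#' median. Censoring times are uniform on (0, b), with b solved numerically
#' so the expected censoring fraction matches `censoring_rate`.
#'
#' @param config A [synthetic_config()].
#' @param em Tumor-bearing [expression_matrix()] (the sequencing mRNA
#'   cohort).
#' @param prognostic_genes Genes to plant; default the first `n_prognostic`
#'   gene ids of the matrix (callers normally pass planted network genes).
#' @return List with `clinical` (data frame `sample_id`, `os_time`,
#'   `os_event`) and `prognostic` (data frame `gene_id`, `hazard_ratio`).
#' @export
generate_clinical <- function(config, em, prognostic_genes = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"),
            inherits(em, "ExpressionMatrix"))
  set.seed(substream_seed(config$seed, "clinical"))
  tumor <- names(em$groups)[em$groups == "tumor"]
  if (!length(tumor)) stop("no tumor samples to attach survival to")
  if (is.null(prognostic_genes))
    prognostic_genes <- utils::head(rownames(em$values), config$n_prognostic)
  prognostic_genes <- utils::head(prognostic_genes, config$n_prognostic)

  log_h <- rep(log(config$baseline_hazard), length(tumor))
  for (g in prognostic_genes) {
    x <- em$values[g, tumor]
    z <- as.numeric(x > stats::median(x))
    log_h <- log_h + log(config$hazard_ratio) * z
  }
  h <- exp(log_h)
  t_true <- stats::rexp(length(tumor), rate = h)

  rate <- config$censoring_rate
  if (rate <= 0) {
    os_time <- t_true
    os_event <- rep(1, length(tumor))
  } else if (rate >= 0.999) {
    os_time <- stats::runif(length(tumor), 0, 1 / config$baseline_hazard)
    os_event <- rep(0, length(tumor))
  } else {
    cens_frac <- function(b) mean((1 - exp(-h * b)) / (h * b)) - rate
    b <- stats::uniroot(cens_frac, lower = 1e-9 / config$baseline_hazard,
                        upper = 1e6 / config$baseline_hazard, tol = 1e-8)$root
    c_time <- stats::runif(length(tumor), 0, b)
    os_event <- as.numeric(t_true <= c_time)
    os_time <- pmin(t_true, c_time)
  }
  list(clinical = data.frame(sample_id = tumor, os_time = os_time,
                             os_event = os_event, stringsAsFactors = FALSE),
       prognostic = data.frame(gene_id = prognostic_genes,
                               hazard_ratio = rep(config$hazard_ratio,
                                                  length(prognostic_genes)),
                               stringsAsFactors = FALSE))
}

#' Generate cell-line expression and an IC50 drug-response matrix
#'
#' Cell-line expression of every mRNA feature plus an IC50 matrix
#' (natural-log scale). For each planted gene-drug pair the IC50 is a linear
#' function of standardized expression with slope sign `drug_effect_sign`
#' and signal-to-noise `drug_effect`; all other entries are independent
#' noise. A missingness mask is applied at `drug_missing_rate`.
#'
#' @param config A [synthetic_config()].
#' @param planted_genes Genes to receive planted drug associations; default
#'   the first mRNA feature ids (callers normally pass prognostic genes).
#' @return List with `cell_line_expr` ([expression_matrix()]-like numeric
#'   matrix, genes x cell lines), `drugs` (a `DrugResponseMatrix`) and
#'   `drug_pairs` (data frame `gene_id`, `drug_id`, `sign`).
#' @export
generate_drug_response <- function(config, planted_genes = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(substream_seed(config$seed, "drugs"))
  genes <- synthetic_feature_ids(config$n_features)$mRNA
  lines <- sprintf("CL_s%03d", seq_len(config$n_cell_lines))
  expr <- matrix(stats::runif(length(genes), config$baseline_range[1],
                              config$baseline_range[2]) +
                   stats::rnorm(length(genes) * length(lines)),
                 length(genes), length(lines),
                 dimnames = list(genes, lines))
  drugs <- sprintf("drug_s%02d", seq_len(config$n_drugs))
  ic50 <- matrix(stats::rnorm(length(lines) * length(drugs),
                              mean = rep(stats::runif(length(drugs), 0, 4),
                                         each = length(lines)), sd = 1),
                 length(lines), length(drugs),
                 dimnames = list(lines, drugs))
  if (is.null(planted_genes)) planted_genes <- utils::head(genes, config$n_drug_pairs)
  planted_genes <- utils::head(planted_genes, config$n_drug_pairs)
  pairs <- data.frame(gene_id = character(), drug_id = character(),
                      sign = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(planted_genes)) {
    g <- planted_genes[i]
    d <- drugs[i]
    z <- as.numeric(scale(expr[g, ]))
    ic50[, d] <- stats::rnorm(length(lines), sd = 1) +
      config$drug_effect_sign * config$drug_effect * z
    pairs <- rbind(pairs, data.frame(gene_id = g, drug_id = d,
                                     sign = config$drug_effect_sign,
                                     stringsAsFactors = FALSE))
  }
  if (config$drug_missing_rate > 0) {
    mask <- matrix(stats::runif(length(ic50)) < config$drug_missing_rate,
                   nrow(ic50), ncol(ic50))
    ic50[mask] <- NA
  }
  list(cell_line_expr = expr,
       drugs = drug_response_matrix(ic50, "ln_ic50"),
       drug_pairs = pairs)
}

#' Generate a complete synthetic study with its ground-truth manifest
#'
#' Runs every generator under named seed substreams and assembles the
#' ground-truth manifest: planted DE features with directions, planted
#' triplets, decoys with their violated condition, prognostic genes with
#' true hazard ratios, and planted drug-gene pairs with their sign.
#'
#' @param config A [synthetic_config()].
#' @return A `SyntheticStudy` list: `config`, `cohorts`, `mc_pairs`,
#'   `mg_pairs`, `gene_sets`, `clinical`, `cell_line_expr`, `drugs` and
#'   `manifest`.
#' @export
generate_synthetic_study <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  expr <- generate_expression(config)
  net <- generate_interactions(config, expr$de)
  gene_sets <- generate_gene_sets(config, net$triplets)
  prognostic_genes <- unique(net$triplets$gene_id)
  if (!length(prognostic_genes))
    prognostic_genes <- utils::head(expr$de$feature_id[expr$de$kind == "mRNA"],
                                    config$n_prognostic)
  clin <- generate_clinical(config, expr$cohorts$mrna_seq, prognostic_genes)
  drg <- generate_drug_response(config, clin$prognostic$gene_id)
  manifest <- list(seed = config$seed,
                   de = expr$de,
                   triplets = net$triplets,
                   decoys = net$decoys,
                   planted_set = "SET_SYNTH_PLANTED",
                   prognostic = clin$prognostic,
                   drug_pairs = drg$drug_pairs)
  structure(list(config = config, cohorts = expr$cohorts,
                 mc_pairs = net$mc_pairs, mg_pairs = net$mg_pairs,
                 gene_sets = gene_sets, clinical = clin$clinical,
                 cell_line_expr = drg$cell_line_expr, drugs = drg$drugs,
                 manifest = manifest),
            class = "SyntheticStudy")
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Expression TSVs and sample sheets per cohort, interaction tables, GMT
#' gene sets, clinical table, cell-line expression, drug matrix, and the
#' ground-truth manifest as JSON (with the seed and configuration echoed).
#'
#' @param study A `SyntheticStudy` from [generate_synthetic_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "SyntheticStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  for (nm in names(study$cohorts)) {
    write_expression_table(study$cohorts[[nm]], p(paste0(nm, "_expr.tsv")))
    write_sample_sheet(study$cohorts[[nm]], p(paste0(nm, "_samples.tsv")))
  }
  write_interaction_table(study$mc_pairs, p("mirna_circ_pairs.tsv"))
  write_interaction_table(study$mg_pairs, p("mirna_gene_pairs.tsv"))
  write_gene_sets_gmt(study$gene_sets, p("gene_sets.gmt"))
  write_clinical_table(study$clinical, p("clinical.tsv"))
  cl_em <- expression_matrix(
    study$cell_line_expr,
    stats::setNames(rep("tumor", ncol(study$cell_line_expr)),
                    colnames(study$cell_line_expr)),
    kind = "mRNA")
  write_expression_table(cl_em, p("cell_line_expr.tsv"))
  write_drug_matrix(study$drugs, p("drug_ic50.tsv"))
  cfg <- study$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg, manifest = study$manifest),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
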