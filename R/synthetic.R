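#' Simulation configuration for synthetic single-cell cohorts
#'
#' Builds and validates the parameter set for [generate_cohort()] and
#' friends. The generator emulates the structure the downstream analyses
#' assume: tumor-of-origin groups, logistic dropout, coexpressed gene
#' modules, a latent stemness gradient acting on a planted signature set,
#' per-subtype classifier-gene shifts (with optional hybrid cells carrying a
#' half-effect secondary subtype), and per-gene splice-variant proportions
#' drawn from a symmetric Dirichlet.
#'
#' Expression is modelled on the log2 scale: for gene g in cell c the
#' underlying mean is
#' `mu = baseline_g + group_shift(g, group(c)) + module_shift * activity_m(c)
#'  + stemness_effect * latent(c) [signature genes]
#'  + subtype effect [classifier genes]`,
#' the observed value is `TPM = max(2^(mu + noise) - 1, 0)`, and detection is
#' Bernoulli with probability `plogis(dropout_steepness * (mu -
#' dropout_midpoint))` so weakly expressed genes drop out more often.
#'
#' @param n_groups number of tumors/lines of origin.
#' @param cells_per_group single cells per group.
#' @param n_lnc,n_coding number of lncRNA / protein-coding genes.
#' @param baseline_log_mean,baseline_log_sd log2-scale baseline expression
#'   distribution across genes.
#' @param noise_sd per-observation log2-scale noise.
#' @param dropout_midpoint,dropout_steepness logistic dropout parameters on
#'   the underlying log2 mean.
#' @param group_shift_sd sd of per-(gene, group) mean shifts.
#' @param n_modules,module_size,module_shift coexpression modules: each
#'   module has a per-cell standard-normal activity scaled by `module_shift`
#'   and added to its member genes.
#' @param stemness_set_size,stemness_effect size of the planted stemness
#'   signature and the log2 effect of the latent stemness value on it.
#' @param subtype_sets named list with `sizes` and `effects`, length-4
#'   numeric vectors for the proneural (PN), neural (N), mesenchymal (MES)
#'   and classical (CL) classifier sets.
#' @param hybrid_frac fraction of cells receiving a secondary subtype label
#'   at half effect.
#' @param n_multivariant_genes,variants_per_gene,dirichlet_concentration
#'   splicing parameters: how many genes carry `variants_per_gene`
#'   transcripts and the symmetric Dirichlet concentration of their
#'   within-gene variant proportions (small values give single-variant
#'   dominance).
#' @param proportion_floor drawn variant proportions below this value are
#'   zeroed (variants without expression) and the rest renormalized.
#' @param seed integer RNG seed; all randomness flows from it through
#'   per-component sub-streams.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_groups = 5, cells_per_group = 40,
                       n_lnc = 2000, n_coding = 0,
                       baseline_log_mean = 4, baseline_log_sd = 1.5,
                       noise_sd = 1,
                       dropout_midpoint = 1, dropout_steepness = 1,
                       group_shift_sd = 0.5,
                       n_modules = 4, module_size = 50, module_shift = 1,
                       stemness_set_size = 30, stemness_effect = 2,
                       subtype_sets = list(sizes = rep(30L, 4),
                                           effects = rep(2, 4)),
                       hybrid_frac = 0.2,
                       n_multivariant_genes = 30, variants_per_gene = 12,
                       dirichlet_concentration = 0.3,
                       proportion_floor = 0.01,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_groups = n_groups, cells_per_group = cells_per_group,
              n_lnc = n_lnc, stemness_set_size = stemness_set_size,
              n_multivariant_genes = n_multivariant_genes,
              variants_per_gene = variants_per_gene)
  if (any(counts <= 0) || n_coding < 0 || n_modules < 0 || module_size < 0)
    stop("configuration error: counts must be positive")
  if (variants_per_gene < 2)
    stop("configuration error: variants_per_gene must be >= 2")
  effects <- c(stemness_effect, module_shift, subtype_sets$effects)
  if (any(effects < 0)) stop("configuration error: effects must be >= 0")
  if (dropout_steepness <= 0)
    stop("configuration error: dropout_steepness must be > 0")
  if (length(subtype_sets$sizes) != 4 || length(subtype_sets$effects) != 4)
    stop("configuration error: subtype_sets needs 4 sizes and 4 effects")
  if (hybrid_frac < 0 || hybrid_frac > 1)
    stop("configuration error: hybrid_frac must be in [0,1]")
  planted <- stemness_set_size + sum(subtype_sets$sizes)
  if (planted + n_modules * module_size > n_lnc + n_coding)
    stop("configuration error: planted gene lists exceed gene count")
  if (planted > n_lnc)
    stop("configuration error: signature and classifier sets exceed n_lnc")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "SimConfig"
  cfg
}

subtype_labels <- c("PN", "N", "MES", "CL")

# Deterministic per-component sub-seeds so that, e.g., the Dirichlet stream
# does not shift when the expression stream changes.
sim_substreams <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("genes", "latents", "expression", "dropout", "dirichlet",
                "extra")
  s
}

#' Generate a synthetic single-cell cohort with planted structure
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   `expr` (TPM `ExpressionMatrix`, genes x cells),
#'   `meta` (`SampleMetadata`, all `single_cell`),
#'   `annot` (`GeneAnnotation` with the lncRNA / protein-coding split and
#'   gene-to-transcript lists), and
#'   `truth` (planted structure: per-cell `stemness_latent` in \[0,1\],
#'   `subtype_primary` / `subtype_secondary` labels, `group_of_origin`,
#'   per-gene `module_membership`, `signature_genes`, `classifier_genes`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  ss <- sim_substreams(config$seed)
  n_genes <- config$n_lnc + config$n_coding
  n_cells <- config$n_groups * config$cells_per_group
  gene_ids <- c(sprintf("LNC%04d", seq_len(config$n_lnc)),
                if (config$n_coding > 0) sprintf("PC%04d", seq_len(config$n_coding)))
  biotype <- rep(c("lncRNA", "protein_coding"),
                 c(config$n_lnc, config$n_coding))
  groups <- rep(sprintf("T%d", seq_len(config$n_groups)),
                each = config$cells_per_group)
  cell_ids <- paste0(groups, "_C",
                     rep(seq_len(config$cells_per_group), config$n_groups))

  # planted gene lists: signature, 4 classifier sets, modules -- all disjoint
  set.seed(ss["genes"])
  lnc_pool <- sample(gene_ids[seq_len(config$n_lnc)])
  sig_genes <- lnc_pool[seq_len(config$stemness_set_size)]
  used <- config$stemness_set_size
  classifier_genes <- list()
  for (i in 1:4) {
    k <- config$subtype_sets$sizes[i]
    classifier_genes[[subtype_labels[i]]] <- lnc_pool[used + seq_len(k)]
    used <- used + k
  }
  remaining <- c(lnc_pool[-seq_len(used)],
                 if (config$n_coding > 0) sample(gene_ids[config$n_lnc + seq_len(config$n_coding)]))
  module_membership <- rep(NA_integer_, n_genes)
  names(module_membership) <- gene_ids
  if (config$n_modules > 0 && config$module_size > 0) {
    for (m in seq_len(config$n_modules)) {
      mg <- remaining[(m - 1) * config$module_size + seq_len(config$module_size)]
      module_membership[mg] <- m
    }
  }
  baseline <- stats::rnorm(n_genes, config$baseline_log_mean,
                           config$baseline_log_sd)
  group_shift <- matrix(stats::rnorm(n_genes * config$n_groups,
                                     0, config$group_shift_sd),
                        n_genes, config$n_groups)

  set.seed(ss["latents"])
  latent <- stats::runif(n_cells)
  primary <- sample(subtype_labels, n_cells, replace = TRUE)
  secondary <- rep(NA_character_, n_cells)
  hybrid <- stats::runif(n_cells) < config$hybrid_frac
  if (any(hybrid))
    secondary[hybrid] <- vapply(primary[hybrid], function(p)
      sample(setdiff(subtype_labels, p), 1L), character(1))
  module_activity <- matrix(stats::rnorm(max(config$n_modules, 1) * n_cells),
                            max(config$n_modules, 1), n_cells)

  # underlying log2 mean per (gene, cell)
  mu <- matrix(baseline, n_genes, n_cells) +
    group_shift[, rep(seq_len(config$n_groups), each = config$cells_per_group)]
  if (config$n_modules > 0 && config$module_size > 0) {
    in_mod <- which(!is.na(module_membership))
    mu[in_mod, ] <- mu[in_mod, ] +
      config$module_shift * module_activity[module_membership[in_mod], ]
  }
  sig_idx <- match(sig_genes, gene_ids)
  mu[sig_idx, ] <- mu[sig_idx, ] +
    config$stemness_effect * matrix(latent, length(sig_idx), n_cells,
                                    byrow = TRUE)
  for (i in 1:4) {
    s <- subtype_labels[i]
    idx <- match(classifier_genes[[s]], gene_ids)
    eff <- config$subtype_sets$effects[i]
    bump <- eff * (primary == s) + (eff / 2) * (!is.na(secondary) & secondary == s)
    mu[idx, ] <- mu[idx, ] + matrix(bump, length(idx), n_cells, byrow = TRUE)
  }

  set.seed(ss["expression"])
  noise <- matrix(stats::rnorm(n_genes * n_cells, 0, config$noise_sd),
                  n_genes, n_cells)
  tpm <- pmax(2^(mu + noise) - 1, 0)

  set.seed(ss["dropout"])
  p_detect <- stats::plogis(config$dropout_steepness *
                              (mu - config$dropout_midpoint))
  detected <- matrix(stats::runif(n_genes * n_cells), n_genes, n_cells) < p_detect
  tpm[!detected] <- 0

  dimnames(tpm) <- list(gene_ids, cell_ids)
  expr <- expression_matrix(tpm, "TPM")
  meta <- sample_metadata(cell_ids, groups, rep("single_cell", n_cells))
  tx <- multivariant_transcripts(config, gene_ids)
  annot <- gene_annotation(gene_ids, biotype, tx)
  truth <- list(
    stemness_latent = stats::setNames(latent, cell_ids),
    subtype_primary = stats::setNames(primary, cell_ids),
    subtype_secondary = stats::setNames(secondary, cell_ids),
    group_of_origin = stats::setNames(groups, cell_ids),
    module_membership = module_membership,
    signature_genes = sig_genes,
    classifier_genes = classifier_genes,
    variant_proportions = NULL,
    mu = mu
  )
  list(expr = expr, meta = meta, annot = annot, truth = truth)
}

# the first n_multivariant_genes lncRNAs carry variants_per_gene transcripts,
# every other gene a single one
multivariant_transcripts <- function(config, gene_ids) {
  n_mv <- min(config$n_multivariant_genes, config$n_lnc)
  lapply(seq_along(gene_ids), function(i) {
    k <- if (i <= n_mv) config$variants_per_gene else 1L
    paste0(gene_ids[i], ".", seq_len(k))
  })
}

#' Build paired GSC/DGC population samples from a cohort
#'
#' Emulates matched stem-like (GSC) and differentiated (DGC) culture pairs:
#' per group, the GSC sample is the per-gene mean TPM over the `top_frac`
#' cells with the highest latent stemness, and the DGC sample the mean over
#' the bottom `top_frac`.
#'
#' @param cohort output of [generate_cohort()] (or a TPM `ExpressionMatrix`).
#' @param truth the cohort's truth list (needed when `cohort` is a matrix).
#' @param top_frac fraction of each group's cells averaged into each pool;
#'   must be in (0, 0.5\].
#' @return list with `expr` (TPM `ExpressionMatrix` of 2 x n_groups
#'   population samples) and `meta` (`SampleMetadata` with `pair_id` =
#'   group).
#' @export
generate_population_pairs <- function(cohort, truth = cohort$truth,
                                      top_frac = 0.25) {
  expr <- if (inherits(cohort, "ExpressionMatrix")) cohort else cohort$expr
  if (!(top_frac > 0 && top_frac <= 0.5))
    stop("top_frac must be in (0, 0.5]")
  groups <- truth$group_of_origin[colnames(expr)]
  latent <- truth$stemness_latent[colnames(expr)]
  glev <- unique(groups)
  cols <- list(); ids <- character(0); grp <- character(0); kind <- character(0)
  pair <- character(0)
  for (g in glev) {
    cells <- colnames(expr)[groups == g]
    n <- length(cells)
    if (n < 2 / top_frac)
      stop(sprintf("group %s has %d cells; need at least %g for top_frac %g",
                   g, n, ceiling(2 / top_frac), top_frac))
    k <- floor(top_frac * n)
    ord <- cells[order(latent[cells], decreasing = TRUE)]
    gsc <- rowMeans(unclass(expr)[, ord[seq_len(k)], drop = FALSE])
    dgc <- rowMeans(unclass(expr)[, rev(ord)[seq_len(k)], drop = FALSE])
    cols <- c(cols, list(gsc, dgc))
    ids <- c(ids, paste0(g, "_GSC"), paste0(g, "_DGC"))
    grp <- c(grp, g, g)
    kind <- c(kind, "gsc_culture", "dgc_culture")
    pair <- c(pair, g, g)
  }
  v <- do.call(cbind, cols)
  dimnames(v) <- list(rownames(expr), ids)
  list(expr = expression_matrix(v, "TPM"),
       meta = sample_metadata(ids, grp, kind, pair))
}

#' Build per-group population control samples from a cohort
#'
#' One bulk-like control per group: the per-gene mean TPM over all of the
#' group's cells.
#' @inheritParams generate_population_pairs
#' @return list with `expr` and `meta` (`kind = "population_control"`).
#' @export
generate_population_controls <- function(cohort, truth = cohort$truth) {
  expr <- if (inherits(cohort, "ExpressionMatrix")) cohort else cohort$expr
  groups <- truth$group_of_origin[colnames(expr)]
  glev <- unique(groups)
  v <- vapply(glev, function(g)
    rowMeans(unclass(expr)[, groups == g, drop = FALSE]),
    numeric(nrow(expr)))
  colnames(v) <- paste0(glev, "_ctrl")
  list(expr = expression_matrix(v, "TPM"),
       meta = sample_metadata(colnames(v), glev,
                              rep("population_control", length(glev))))
}

#' Generate transcript-level variant profiles
#'
#' Splits gene-level TPM across annotated transcripts by a symmetric
#' Dirichlet draw per (gene, cell). Proportions below `proportion_floor` are
#' set to exactly zero (variants without expression) and the remainder
#' renormalized, so transcript TPMs always sum to the gene TPM.
#'
#' @param config a [sim_config()]; `dirichlet_concentration` controls
#'   dominance (small values concentrate mass on one variant).
#' @param cohort optional [generate_cohort()] output; when given, the
#'   multivariant genes' TPM rows and cell ids are taken from it, otherwise
#'   gene-level TPMs are simulated from the config's expression model.
#' @return list with `expr` (transcript-level TPM `ExpressionMatrix`),
#'   `g2t` (data.frame gene_id, transcript_id) and `proportions` (list of
#'   per-gene variants x cells proportion matrices, the planted truth).
#' @export
generate_variant_profiles <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$variants_per_gene < 2)
    stop("configuration error: variants_per_gene must be >= 2")
  ss <- sim_substreams(config$seed)
  k <- config$variants_per_gene
  n_mv <- config$n_multivariant_genes
  if (!is.null(cohort)) {
    gene_ids <- rownames(cohort$expr)[seq_len(min(n_mv, config$n_lnc))]
    gene_tpm <- unclass(cohort$expr)[gene_ids, , drop = FALSE]
  } else {
    gene_ids <- sprintf("LNC%04d", seq_len(n_mv))
    n_cells <- config$n_groups * config$cells_per_group
    cell_ids <- paste0(rep(sprintf("T%d", seq_len(config$n_groups)),
                           each = config$cells_per_group),
                       "_C", rep(seq_len(config$cells_per_group),
                                 config$n_groups))
    set.seed(ss["extra"])
    mu <- matrix(stats::rnorm(n_mv * n_cells, config$baseline_log_mean,
                              config$baseline_log_sd), n_mv, n_cells)
    gene_tpm <- pmax(2^(mu + stats::rnorm(n_mv * n_cells, 0, config$noise_sd)) - 1, 0)
    detected <- matrix(stats::runif(n_mv * n_cells), n_mv, n_cells) <
      stats::plogis(config$dropout_steepness * (mu - config$dropout_midpoint))
    gene_tpm[!detected] <- 0
    dimnames(gene_tpm) <- list(gene_ids, cell_ids)
  }
  n_cells <- ncol(gene_tpm)
  set.seed(ss["dirichlet"])
  tx_rows <- list(); props <- list()
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    # symmetric Dirichlet via normalized gammas, one draw per cell
    draw <- matrix(stats::rgamma(k * n_cells, shape = config$dirichlet_concentration),
                   k, n_cells)
    p <- sweep(draw, 2, colSums(draw), "/")
    p[p < config$proportion_floor] <- 0
    p <- sweep(p, 2, colSums(p), "/")
    tx <- sweep(p, 2, gene_tpm[g, ], "*")
    rownames(tx) <- paste0(g, ".", seq_len(k))
    rownames(p) <- rownames(tx)
    colnames(p) <- colnames(gene_tpm)
    tx_rows[[g]] <- tx
    props[[g]] <- p
  }
  v <- do.call(rbind, tx_rows)
  colnames(v) <- colnames(gene_tpm)
  g2t <- data.frame(
    gene_id = rep(gene_ids, each = k),
    transcript_id = unlist(lapply(gene_ids, function(g) paste0(g, ".", seq_len(k)))),
    stringsAsFactors = FALSE)
  list(expr = expression_matrix(v, "TPM"), g2t = g2t, proportions = props)
}

#' Write a cohort to disk
#'
#' Expression TSV, metadata TSV, gene-to-transcript map TSV and truth JSON;
#' optionally an MTX triplet.
#' @param cohort output of [generate_cohort()].
#' @param dir output directory.
#' @param mtx also write the MTX triplet.
#' @export
write_cohort <- function(cohort, dir, mtx = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(cohort$expr, file.path(dir, "expression.tsv"))
  write_metadata_tsv(cohort$meta, file.path(dir, "metadata.tsv"))
  utils::write.table(gene_transcript_map(cohort$annot),
                     file.path(dir, "gene2tx.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$mu <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (mtx) write_expression_mtx(cohort$expr, file.path(dir, "mtx"))
  invisible(dir)
}
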