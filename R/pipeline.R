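#' Validate a pipeline configuration
#'
#' Checks the stage blocks, fills defaults and verifies that referenced
#' input files exist. Errors name the offending field path.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognized blocks: `seed`, `outdir`, `simulate` (logical
#'   `enabled` plus [sim_config()] overrides), `inputs` (`expression`,
#'   `metadata`, optionally `population`, `population_metadata`, `gene2tx`,
#'   `transcripts`, `classifiers` GMT), `preprocess`, `structure`, `som`,
#'   `splicing`, `signatures`.
#' @return the normalized configuration list, invisibly classed
#'   `PipelineConfig`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config: must be a list or YAML path")
  defaults <- list(
    seed = 1L,
    outdir = "lncsom_out",
    simulate = list(enabled = TRUE),
    inputs = list(),
    preprocess = list(thr_all = 2, thr_group = 4, min_frac = 0.5,
                      include_population = TRUE),
    structure = list(top_n = 500, top_k_abundant = 50,
                     linkage = "average", distance = "correlation"),
    som = list(train_frac = 0.25, train_n = NULL, epochs = 200,
               alpha = c(0.05, 0.01), n_pcs = 10,
               neighborhood = "bubble"),
    splicing = list(min_variants = 10, dom_threshold = 0.5),
    signatures = list(alpha = 0.05, n_random = 100, q = 0.01,
                      top_frac = 0.25))
  for (block in names(defaults)) {
    if (is.null(config[[block]])) config[[block]] <- defaults[[block]]
    else if (is.list(defaults[[block]])) {
      unknown <- setdiff(names(config[[block]]),
                         c(names(defaults[[block]]),
                           if (block == "simulate") names(formals(sim_config)),
                           if (block == "inputs")
                             c("expression", "metadata", "population",
                               "population_metadata", "gene2tx",
                               "transcripts", "classifiers")))
      if (length(unknown) > 0)
        stop(sprintf("config field %s.%s is not recognized",
                     block, unknown[1]))
      for (f in names(defaults[[block]]))
        if (is.null(config[[block]][[f]]))
          config[[block]][[f]] <- defaults[[block]][[f]]
    }
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config field seed: must be a single integer")
  config$seed <- as.integer(config$seed)
  sim_on <- isTRUE(config$simulate$enabled)
  if (!sim_on) {
    for (f in c("expression", "metadata")) {
      path <- config$inputs[[f]]
      if (is.null(path))
        stop(sprintf("config field inputs.%s: required when simulate is disabled", f))
      if (!file.exists(path))
        stop(sprintf("config field inputs.%s: file not found: %s", f, path))
    }
    for (f in c("population", "population_metadata", "gene2tx",
                "transcripts", "classifiers")) {
      path <- config$inputs[[f]]
      if (!is.null(path) && !file.exists(path))
        stop(sprintf("config field inputs.%s: file not found: %s", f, path))
    }
  }
  if (config$signatures$q <= 0 || config$signatures$q >= 0.5)
    stop("config field signatures.q: must lie in (0, 0.5)")
  class(config) <- c("PipelineConfig", "list")
  invisible(config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full heterogeneity pipeline
#'
#' Executes simulate (optional), preprocess, structure, SOM, splicing and
#' signatures stages in order, writing each stage's tables under
#' `outdir/<stage>/` and a JSON run manifest (package version, parameters,
#' per-stage status, output checksums) at `outdir/manifest.json`. Any stage
#' failure halts the run with the manifest recording the completed stages.
#' All randomness derives from the single config seed, so a rerun with the
#' same config reproduces every output byte for byte.
#'
#' @param config a [validate_pipeline_config()] input (list or YAML path).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- list(
    package = "lncsom",
    version = as.character(utils::packageVersion("lncsom")),
    parameters = unclass(config),
    stages = list())
  state <- new.env(parent = emptyenv())

  finish <- function(status) {
    files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                          "manifest.json"))
    manifest$checksums <- as.list(tools::md5sum(file.path(outdir, files)))
    names(manifest$checksums) <- files
    manifest$status <- status
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    manifest
  }
  run_stage <- function(name, fun) {
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) paste("failed:", conditionMessage(e)))
    manifest$stages[[name]] <<- res
    if (res != "ok") {
      finish("failed")
      stop(sprintf("stage %s %s", name, res), call. = FALSE)
    }
  }

  run_stage("simulate", function() pipeline_simulate(config, state, outdir))
  run_stage("preprocess", function() pipeline_preprocess(config, state, outdir))
  run_stage("structure", function() pipeline_structure(config, state, outdir))
  run_stage("som", function() pipeline_som(config, state, outdir))
  run_stage("splicing", function() pipeline_splicing(config, state, outdir))
  run_stage("signatures", function() pipeline_signatures(config, state, outdir))
  invisible(finish("ok"))
}

pipeline_simulate <- function(config, state, outdir) {
  if (!isTRUE(config$simulate$enabled)) {
    state$expr <- read_expression_tsv(config$inputs$expression, "TPM")
    state$meta <- read_metadata_tsv(config$inputs$metadata)
    if (!is.null(config$inputs$population)) {
      state$pop <- read_expression_tsv(config$inputs$population, "TPM")
      state$pop_meta <- read_metadata_tsv(config$inputs$population_metadata)
    }
    if (!is.null(config$inputs$transcripts)) {
      state$tx <- read_expression_tsv(config$inputs$transcripts, "TPM")
      state$g2t <- utils::read.delim(config$inputs$gene2tx,
                                     stringsAsFactors = FALSE)
    }
    if (!is.null(config$inputs$classifiers))
      state$classifiers <- read_gmt(config$inputs$classifiers)
    return(invisible())
  }
  args <- config$simulate
  args$enabled <- NULL
  args$seed <- config$seed
  cfg <- do.call(sim_config, args)
  cohort <- generate_cohort(cfg)
  pairs <- generate_population_pairs(cohort, top_frac = config$signatures$top_frac)
  ctrls <- generate_population_controls(cohort)
  var_prof <- generate_variant_profiles(cfg, cohort)
  dir <- file.path(outdir, "simulate")
  write_cohort(cohort, dir)
  write_expression_tsv(pairs$expr, file.path(dir, "population_pairs.tsv"))
  write_metadata_tsv(rbind(pairs$meta, ctrls$meta),
                     file.path(dir, "population_metadata.tsv"))
  write_expression_tsv(ctrls$expr, file.path(dir, "population_controls.tsv"))
  write_expression_tsv(var_prof$expr, file.path(dir, "transcripts.tsv"))
  # planted module gene sets double as a demo GMT collection
  mm <- cohort$truth$module_membership
  mods <- split(names(mm)[!is.na(mm)], mm[!is.na(mm)])
  if (length(mods) > 0)
    write_gmt(stats::setNames(mods, paste0("MODULE_", names(mods))),
              file.path(dir, "modules.gmt"))
  state$expr <- cohort$expr
  state$meta <- cohort$meta
  state$annot <- cohort$annot
  state$truth <- cohort$truth
  state$pop <- expression_matrix(cbind(unclass(pairs$expr), unclass(ctrls$expr)),
                                 "TPM")
  state$pop_meta <- rbind(pairs$meta, ctrls$meta)
  state$tx <- var_prof$expr
  state$g2t <- var_prof$g2t
  state$classifiers <- cohort$truth$classifier_genes
  state$gene_sets <- mods
  invisible()
}

pipeline_preprocess <- function(config, state, outdir) {
  pp <- config$preprocess
  res <- preprocess_cohort(state$expr, state$meta, pop = state$pop,
                           thr_all = pp$thr_all, thr_group = pp$thr_group,
                           min_frac = pp$min_frac,
                           include_population = isTRUE(pp$include_population))
  dir <- file.path(outdir, "preprocess")
  dir.create(dir, showWarnings = FALSE)
  writeLines(res$genes, file.path(dir, "selected_genes.txt"))
  writeLines(res$cells, file.path(dir, "retained_cells.txt"))
  write_expression_tsv(res$z, file.path(dir, "zscores.tsv"))
  state$pp <- res
  state$z_cells <- expr_subset(res$z, samples = res$cells)
  invisible()
}

pipeline_structure <- function(config, state, outdir) {
  st <- config$structure
  dir <- file.path(outdir, "structure")
  dir.create(dir, showWarnings = FALSE)
  pe <- percent_expressed(expr_subset(state$pp$log, samples = state$pp$cells))
  write_tsv(data.frame(cell_id = names(pe), frac_expressed = pe),
            file.path(dir, "percent_expressed.tsv"))
  cs <- pairwise_correlations(expr_subset(state$pp$log,
                                          samples = state$pp$cells),
                              state$meta)
  write_tsv(cs$pairs, file.path(dir, "correlations.tsv"))
  n <- min(st$top_n, length(state$pp$genes))
  panel <- top_variance_genes(state$pp$log, n)
  writeLines(panel, file.path(dir, "top_variance_genes.txt"))
  pca <- run_pca(expr_subset(state$pp$log, samples = state$pp$cells), panel)
  write_tsv(data.frame(cell_id = rownames(pca$coords), pca$coords),
            file.path(dir, "pca_coords.tsv"))
  state$train_panel <- panel
  if (!is.null(state$pop_meta)) {
    ctrl <- state$pop_meta$sample_id[state$pop_meta$kind == "population_control"]
    if (length(ctrl) > 0) {
      logc <- expr_subset(log_transform(expr_subset(state$pop, samples = ctrl)),
                          features = state$pp$genes)
      k <- min(st$top_k_abundant, nrow(logc))
      union_panel <- top_abundant_union(logc, k)
      writeLines(union_panel, file.path(dir, "abundance_union_genes.txt"))
      hc <- hier_cluster(expr_subset(logc, features = union_panel),
                         linkage = st$linkage, distance = st$distance)
      write_dendrogram_newick(hc$row_hclust, file.path(dir, "gene_dendrogram.nwk"))
    }
  }
  invisible()
}

pipeline_som <- function(config, state, outdir) {
  sm <- config$som
  dir <- file.path(outdir, "som")
  dir.create(dir, showWarnings = FALSE)
  z <- unclass(state$z_cells)
  train_n <- if (!is.null(sm$train_n)) sm$train_n
  else max(4, round(sm$train_frac * nrow(z)))
  train_genes <- top_variance_genes(state$z_cells, min(train_n, nrow(z)))
  dims <- som_grid_size(length(train_genes))
  grid <- som_grid(dims["xdim"], dims["ydim"])
  grid <- som_init(grid, z[train_genes, , drop = FALSE], n_pcs = sm$n_pcs,
                   seed = config$seed)
  grid <- som_train(grid, z[train_genes, , drop = FALSE], epochs = sm$epochs,
                    alpha = sm$alpha, neighborhood = sm$neighborhood,
                    seed = config$seed)
  mapping <- som_map(grid, z)
  u <- compute_umatrix(grid)
  cl <- som_cluster_units(grid, u)
  gene_cl <- som_gene_clusters(mapping, cl)
  write_tsv(data.frame(unit = seq_len(nrow(grid$codebook)), grid$codebook),
            file.path(dir, "codebook.tsv"))
  write_tsv(cbind(mapping, cluster = gene_cl[mapping$gene_id]),
            file.path(dir, "gene_units.tsv"))
  write_tsv(data.frame(unit = seq_along(u), u = u,
                       cluster = cl$unit_cluster),
            file.path(dir, "umatrix.tsv"))
  comp <- vapply(colnames(z), function(cell)
    cell_component(mapping, state$z_cells, cell,
                   n_units = grid$xdim * grid$ydim), numeric(dims["xdim"] * dims["ydim"]))
  write_tsv(data.frame(unit = seq_len(nrow(comp)), comp, check.names = FALSE),
            file.path(dir, "cell_components.tsv"))
  if (!is.null(state$gene_sets) && length(state$gene_sets) > 0) {
    universe <- rownames(z)
    enr <- lapply(sort(unique(gene_cl)), function(k) {
      res <- enrich_cluster(names(gene_cl)[gene_cl == k],
                            state$gene_sets, universe)
      cbind(cluster = k, res)
    })
    write_tsv(do.call(rbind, enr), file.path(dir, "cluster_enrichment.tsv"))
  }
  state$grid <- grid
  state$mapping <- mapping
  invisible()
}

pipeline_splicing <- function(config, state, outdir) {
  if (is.null(state$tx)) return(invisible())
  sp <- config$splicing
  dir <- file.path(outdir, "splicing")
  dir.create(dir, showWarnings = FALSE)
  mv <- select_multivariant_genes(state$g2t, sp$min_variants)
  writeLines(mv, file.path(dir, "multivariant_genes.txt"))
  if (length(mv) == 0) return(invisible())
  g2t_mv <- state$g2t[state$g2t$gene_id %in% mv, ]
  tab <- relative_abundance(state$tx, g2t_mv)
  write_tsv(tab, file.path(dir, "relative_abundance.tsv"))
  dom <- dominant_variants(tab, sp$dom_threshold)
  write_tsv(dom$per_gene, file.path(dir, "dominant_variants.tsv"))
  write_tsv(data.frame(gene_id = names(dom$n_dominant_variants),
                       n_dominant_variants = dom$n_dominant_variants),
            file.path(dir, "dominance_counts.tsv"))
  freq <- variant_frequency(tab, all_transcripts = g2t_mv$transcript_id)
  write_tsv(data.frame(transcript_id = names(freq), n_cells = freq),
            file.path(dir, "variant_frequency.tsv"))
  vpc <- variants_per_cell(tab, mv[1])
  write_tsv(data.frame(cell_id = names(vpc), n_variants = vpc),
            file.path(dir, "variants_per_cell.tsv"))
  phi <- variant_association(tab, mv[1])
  write_tsv(data.frame(transcript_id = rownames(phi), phi,
                       check.names = FALSE),
            file.path(dir, "variant_association.tsv"))
  invisible()
}

pipeline_signatures <- function(config, state, outdir) {
  sg <- config$signatures
  dir <- file.path(outdir, "signatures")
  dir.create(dir, showWarnings = FALSE)
  z <- state$z_cells
  meta_cells <- state$meta[match(colnames(z), state$meta$sample_id), ]
  if (!is.null(state$pop_meta) &&
      sum(state$pop_meta$kind == "gsc_culture") >= 2) {
    log_pop <- log_transform(state$pop)
    sig <- derive_stemness_signature(log_pop, state$pop_meta, alpha = sg$alpha)
    write_tsv(sig$stats, file.path(dir, "signature_stats.tsv"))
    writeLines(sig$genes, file.path(dir, "signature_genes.txt"))
    sig_in_z <- intersect(sig$genes, rownames(z))
    if (length(sig_in_z) > 0) {
      score <- signature_score(z, sig_in_z)
      grad <- gradient_significance(z, sig_in_z,
                                    stats::setNames(meta_cells$group,
                                                    meta_cells$sample_id),
                                    n_random = sg$n_random,
                                    seed = config$seed)
      write_tsv(data.frame(cell_id = names(score), stemness_score = score),
                file.path(dir, "stemness_scores.tsv"))
      write_tsv(grad, file.path(dir, "stemness_gradient.tsv"))
    }
  }
  cls <- state$classifiers
  if (!is.null(cls)) {
    cls <- lapply(cls, intersect, y = rownames(z))
    cls <- cls[lengths(cls) > 0]
    if (length(cls) > 0) {
      scores <- subtype_scores(z, cls)
      cuts <- subtype_cutoffs(z, cls, n_random = sg$n_random, q = sg$q,
                              seed = config$seed)
      calls <- classify_cells(scores, cuts)
      write_tsv(data.frame(cell_id = rownames(scores), scores),
                file.path(dir, "subtype_scores.tsv"))
      jsonlite::write_json(as.list(cuts), file.path(dir, "subtype_cutoffs.json"),
                           auto_unbox = TRUE, digits = NA)
      write_tsv(data.frame(cell_id = names(calls$top),
                           top_subtype = ifelse(is.na(calls$top), "unclassified",
                                                calls$top),
                           n_subtypes = calls$n_subtypes,
                           passing = vapply(calls$passing, paste,
                                            character(1), collapse = ",")),
                file.path(dir, "subtype_calls.tsv"))
    }
  }
  invisible()
}
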