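#' Fraction of a gene panel detected per cell
#'
#' @param m an `ExpressionMatrix` (TPM or LOG2_TPM1; detection means a
#'   strictly positive value, i.e. TPM > 0).
#' @param genes gene ids (subset of the matrix features).
#' @return named numeric vector, per-cell fraction in \[0, 1\].
#' @export
percent_expressed <- function(m, genes = rownames(m)) {
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0)
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  v <- unclass(m)[genes, , drop = FALSE]
  colSums(v > 0) / length(genes)
}

#' Pairwise cell-cell Pearson correlations
#'
#' Correlates every unordered pair of cells over the gene vector
#' (log2(TPM+1) values) and flags pairs as within- or between-group. Cells
#' with a constant expression vector yield undefined correlations; their
#' pairs are reported as NA.
#'
#' @param m `ExpressionMatrix` in LOG2_TPM1 space with >= 2 cells.
#' @param meta `SampleMetadata` covering the cells.
#' @return a `CorrelationSummary`: list with `pairs` (data.frame sample_a,
#'   sample_b, within_group, r) and `by_group` (five-number summaries of the
#'   within-group r distribution per group plus the between-group pool).
#' @export
pairwise_correlations <- function(m, meta) {
  if (ncol(m) < 2) stop("need at least 2 cells")
  check_metadata(m, meta)
  v <- unclass(m)
  constant <- apply(v, 2, stats::sd) == 0
  if (any(constant))
    message(sum(constant), " constant cell vector(s); their correlations are NA")
  cm <- suppressWarnings(stats::cor(v))
  cm[constant, ] <- NA; cm[, constant] <- NA
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  groups <- meta$group[match(colnames(m), meta$sample_id)]
  pairs <- data.frame(
    sample_a = colnames(m)[idx[, 1]],
    sample_b = colnames(m)[idx[, 2]],
    within_group = groups[idx[, 1]] == groups[idx[, 2]],
    r = cm[idx],
    stringsAsFactors = FALSE)
  pairs$group <- ifelse(pairs$within_group, groups[idx[, 1]], NA_character_)
  summarize <- function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(rep(NA_real_, 5))
    stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  }
  grp_names <- unique(groups)
  by_group <- t(vapply(grp_names, function(g)
    summarize(pairs$r[pairs$within_group & pairs$group == g]), numeric(5)))
  by_group <- rbind(by_group, between = summarize(pairs$r[!pairs$within_group]))
  colnames(by_group) <- c("min", "q1", "median", "q3", "max")
  structure(list(pairs = pairs, by_group = by_group),
            class = "CorrelationSummary")
}

#' Top-variance gene panel
#'
#' The `n` genes with the largest variance across samples; ties broken by
#' input order.
#' @param m an `ExpressionMatrix`.
#' @param n panel size (default 500).
#' @return character vector of gene ids.
#' @export
top_variance_genes <- function(m, n = 500) {
  if (n > nrow(m)) stop("n exceeds the number of genes")
  v <- unclass(m)
  vars <- apply(v, 1, stats::var)
  ord <- order(-vars, seq_along(vars))
  rownames(m)[sort(ord[seq_len(n)])]
}

#' PCA of samples in gene space
#'
#' Centered (unscaled) principal component analysis of the samples using the
#' given gene panel.
#' @param m an `ExpressionMatrix`.
#' @param genes gene panel (default: all features).
#' @param n_components number of components to return (default 3; reduced
#'   with a warning when the data support fewer).
#' @return a `PCAResult`: list with `coords` (samples x components),
#'   `var_explained` (fractions, nonincreasing), `genes`.
#' @export
run_pca <- function(m, genes = rownames(m), n_components = 3) {
  if (ncol(m) < 3) stop("PCA needs at least 3 samples")
  v <- t(unclass(expr_subset(m, features = genes)))
  max_comp <- min(nrow(v) - 1, ncol(v))
  if (n_components > max_comp) {
    warning(sprintf("reducing components from %d to %d (rank limit)",
                    n_components, max_comp))
    n_components <- max_comp
  }
  p <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  structure(list(coords = p$x[, seq_len(n_components), drop = FALSE],
                 var_explained = frac[seq_len(n_components)],
                 genes = genes),
            class = "PCAResult")
}

#' Union of per-control most-abundant gene panels
#'
#' For each population control sample, takes the `k` genes with the highest
#' expression in that sample (ties broken by input order), and returns the
#' deduplicated union in feature input order.
#' @param pop `ExpressionMatrix` of population controls (LOG2_TPM1).
#' @param k per-control panel size (default 50).
#' @return character vector of gene ids.
#' @export
top_abundant_union <- function(pop, k = 50) {
  if (ncol(pop) < 1) stop("need at least one population control")
  if (k > nrow(pop)) stop("k exceeds the number of genes")
  v <- unclass(pop)
  sel <- logical(nrow(v))
  for (j in seq_len(ncol(v))) {
    ord <- order(-v[, j], seq_len(nrow(v)))
    sel[ord[seq_len(k)]] <- TRUE
  }
  rownames(pop)[sel]
}

#' Hierarchical clustering of rows and columns
#'
#' @param m an `ExpressionMatrix` (no NaN values).
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward's D2).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @return list with `row_order`, `col_order` (leaf id vectors), `row_hclust`,
#'   `col_hclust`, and the `linkage`/`distance` used.
#' @export
hier_cluster <- function(m, linkage = c("average", "complete", "ward"),
                         distance = c("correlation", "euclidean")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  v <- unclass(m)
  if (any(!is.finite(v))) stop("matrix contains non-finite values")
  method <- if (linkage == "ward") "ward.D2" else linkage
  dfun <- function(x) {
    if (distance == "euclidean") stats::dist(x)
    else stats::as.dist(1 - suppressWarnings(stats::cor(t(x))))
  }
  hr <- stats::hclust(dfun(v), method = method)
  hc <- stats::hclust(dfun(t(v)), method = method)
  list(row_order = rownames(v)[hr$order], col_order = colnames(v)[hc$order],
       row_hclust = hr, col_hclust = hc,
       linkage = linkage, distance = distance)
}

#' Export a dendrogram in Newick format
#' @param hc an `hclust` object (e.g. from [hier_cluster()]).
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
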