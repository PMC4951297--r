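#' log2(TPM + 1) transform
#'
#' Adds a pseudocount of 1 to avoid zeros and log2-transforms, moving a
#' matrix from TPM into LOG2_TPM1 space.
#' @param m an `ExpressionMatrix` in TPM space.
#' @return an `ExpressionMatrix` in LOG2_TPM1 space with unchanged ids.
#' @export
log_transform <- function(m) {
  if (expr_space(m) != "TPM") stop("log_transform expects a TPM-space matrix")
  expression_matrix(log2(unclass(m) + 1), "LOG2_TPM1")
}

#' Two-tier abundance gene filter
#'
#' Keeps genes with average log2(TPM+1) above `thr_all` across all cells, or
#' above `thr_group` within at least one group of origin. Both inequalities
#' are strict. Input order is preserved.
#'
#' @param m `ExpressionMatrix` in LOG2_TPM1 space, restricted to single
#'   cells.
#' @param meta `SampleMetadata` covering the matrix columns; the `group`
#'   column defines the per-group averages.
#' @param thr_all threshold on the mean over all cells (default 2).
#' @param thr_group threshold on the within-group mean (default 4).
#' @return character vector of selected gene ids.
#' @export
select_genes <- function(m, meta, thr_all = 2, thr_group = 4) {
  if (expr_space(m) != "LOG2_TPM1")
    stop("select_genes expects a LOG2_TPM1-space matrix")
  check_metadata(m, meta)
  groups <- meta$group[match(colnames(m), meta$sample_id)]
  v <- unclass(m)
  overall <- rowMeans(v)
  keep <- overall > thr_all
  for (g in unique(groups)) {
    gm <- rowMeans(v[, groups == g, drop = FALSE])
    keep <- keep | (gm > thr_group)
  }
  sel <- rownames(m)[keep]
  if (length(sel) == 0) warning("no genes pass the abundance filter")
  sel
}

#' Cell-retention filter
#'
#' Keeps cells expressing at least `min_frac` of the selected genes, where a
#' gene counts as expressed when its TPM is strictly positive (equivalently
#' log2(TPM+1) > 0). The bound is inclusive ("at least half").
#'
#' @param m `ExpressionMatrix` in LOG2_TPM1 space.
#' @param genes selected gene ids (subset of the matrix features).
#' @param min_frac minimum expressed fraction (default 0.5).
#' @return character vector of retained sample ids.
#' @export
select_cells <- function(m, genes, min_frac = 0.5) {
  if (expr_space(m) != "LOG2_TPM1")
    stop("select_cells expects a LOG2_TPM1-space matrix")
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0)
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  v <- unclass(m)[genes, , drop = FALSE]
  n_expr <- colSums(v > 0)
  colnames(m)[n_expr >= min_frac * length(genes)]
}

#' Per-gene z-score normalization
#'
#' Centers each gene at its mean and scales by its standard deviation over
#' the included samples (sample sd, n-1 denominator). Genes with zero sd
#' carry no cell-to-cell information and are dropped; their ids are recorded
#' in the `dropped` attribute of the result.
#'
#' @param m `ExpressionMatrix` in LOG2_TPM1 space with at least 2 samples.
#' @return `ExpressionMatrix` in ZSCORE space; attribute `dropped` lists the
#'   removed constant genes.
#' @export
zscore <- function(m) {
  if (expr_space(m) != "LOG2_TPM1")
    stop("zscore expects a LOG2_TPM1-space matrix")
  if (ncol(m) < 2) stop("z-scoring needs at least 2 samples")
  v <- unclass(m)
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  constant <- sd == 0
  if (any(constant))
    message(sum(constant), " constant gene(s) dropped during z-scoring")
  z <- (v[!constant, , drop = FALSE] - mu[!constant]) / sd[!constant]
  out <- expression_matrix(z, "ZSCORE")
  attr(out, "dropped") <- rownames(v)[constant]
  out
}

#' Full preprocessing of a single-cell TPM matrix
#'
#' Convenience wrapper: log transform, gene filter, cell filter, then
#' z-score. The z-score statistics are computed jointly over the retained
#' single cells and any population samples passed in `pop` so that both end
#' up on one relative-expression scale; set `include_population = FALSE` to
#' normalize single cells alone.
#'
#' @param tpm single-cell `ExpressionMatrix` in TPM space.
#' @param meta `SampleMetadata` for the single cells.
#' @param pop optional population-sample `ExpressionMatrix` in TPM space
#'   (same feature universe).
#' @param thr_all,thr_group,min_frac filter parameters, see [select_genes()]
#'   and [select_cells()].
#' @param include_population whether population samples enter the z-score
#'   statistics.
#' @return list with `log` (LOG2_TPM1 matrix of retained cells x selected
#'   genes), `z` (ZSCORE matrix, possibly including population columns),
#'   `genes`, `cells`, and `log_pop` (log-space population matrix on the
#'   selected genes, or NULL).
#' @export
preprocess_cohort <- function(tpm, meta, pop = NULL,
                              thr_all = 2, thr_group = 4, min_frac = 0.5,
                              include_population = TRUE) {
  lg <- log_transform(tpm)
  genes <- select_genes(lg, meta, thr_all = thr_all, thr_group = thr_group)
  cells <- select_cells(lg, genes, min_frac = min_frac)
  lg_sel <- expr_subset(lg, features = genes, samples = cells)
  log_pop <- NULL
  zin <- lg_sel
  if (!is.null(pop)) {
    log_pop <- expr_subset(log_transform(pop), features = genes)
    if (include_population) {
      joint <- cbind(unclass(lg_sel), unclass(log_pop))
      zin <- expression_matrix(joint, "LOG2_TPM1")
    }
  }
  list(log = lg_sel, z = zscore(zin), genes = genes, cells = cells,
       log_pop = log_pop)
}
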