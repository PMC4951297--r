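#' Derive a stemness signature from paired GSC/DGC population samples
#'
#' For each gene, the per-pair expression difference (GSC minus matched DGC,
#' log2(TPM+1)) is tested with one paired t-test across the tumor-derived
#' pairs; the signature comprises genes with p below `alpha` and a positive
#' mean difference (up in the stem-like cultures). A gene whose difference
#' is identical across pairs has an undefined t statistic; when that
#' constant difference is positive the gene is included with p recorded as 0
#' and flagged (a perfectly consistent effect). BH-adjusted q-values are
#' reported alongside but not used for selection.
#'
#' `method = "consistent_up"` is an alternative reading that additionally
#' requires the difference to be positive in every single pair.
#'
#' @param pop `ExpressionMatrix` in LOG2_TPM1 space containing the GSC and
#'   DGC samples.
#' @param meta `SampleMetadata`; rows with kind `gsc_culture` /
#'   `dgc_culture` are matched by `pair_id` (>= 2 pairs required).
#' @param alpha p-value threshold (default 0.05).
#' @param method `"paired_t"` (default) or `"consistent_up"`.
#' @return a `SignatureSet` list: `name`, `genes`, `direction`, and a
#'   `stats` data.frame (gene_id, mean_diff, p, q, degenerate flag).
#' @export
derive_stemness_signature <- function(pop, meta, alpha = 0.05,
                                      method = c("paired_t", "consistent_up")) {
  method <- match.arg(method)
  if (expr_space(pop) != "LOG2_TPM1")
    stop("derive_stemness_signature expects LOG2_TPM1 population samples")
  check_metadata(pop, meta)
  gsc <- meta[meta$kind == "gsc_culture" & !is.na(meta$pair_id), ]
  dgc <- meta[meta$kind == "dgc_culture" & !is.na(meta$pair_id), ]
  pairs <- intersect(gsc$pair_id, dgc$pair_id)
  if (length(pairs) < 2)
    stop("need at least 2 GSC/DGC pairs for the paired t-test")
  v <- unclass(pop)
  diffs <- vapply(pairs, function(p)
    v[, gsc$sample_id[match(p, gsc$pair_id)]] -
      v[, dgc$sample_id[match(p, dgc$pair_id)]],
    numeric(nrow(v)))
  mean_diff <- rowMeans(diffs)
  sd_diff <- apply(diffs, 1, stats::sd)
  n <- length(pairs)
  tstat <- mean_diff / (sd_diff / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  degenerate <- sd_diff == 0
  p[degenerate & mean_diff != 0] <- 0  # perfectly consistent effect
  p[degenerate & mean_diff == 0] <- 1
  stats_df <- data.frame(gene_id = rownames(v), mean_diff = mean_diff,
                         p = p, q = stats::p.adjust(p, method = "BH"),
                         degenerate = degenerate, stringsAsFactors = FALSE)
  keep <- stats_df$p < alpha & stats_df$mean_diff > 0
  if (method == "consistent_up")
    keep <- keep & apply(diffs > 0, 1, all)
  structure(list(name = "stemness", genes = stats_df$gene_id[keep],
                 direction = "up_in_gsc", stats = stats_df),
            class = "SignatureSet")
}

#' Construct a signature set
#' @param name signature name.
#' @param genes member gene ids (unique, nonempty).
#' @param direction free-text direction/label (e.g. a subtype).
#' @return a `SignatureSet`.
#' @export
signature_set <- function(name, genes, direction = name) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("empty signature")
  if (anyDuplicated(genes)) stop("duplicate genes in signature")
  structure(list(name = name, genes = genes, direction = direction),
            class = "SignatureSet")
}

#' Signature score per cell
#'
#' The average relative expression (z-score) of the signature genes minus
#' the average relative expression of the whole analysis universe in the
#' same cell. Subtracting the universe mean makes the score invariant to
#' per-cell shifts of all z-scores.
#'
#' @param z `ExpressionMatrix` in ZSCORE space; its rows are the universe.
#' @param sig a `SignatureSet` (or character vector of gene ids).
#' @return named numeric vector of per-cell scores.
#' @export
signature_score <- function(z, sig) {
  genes <- if (inherits(sig, "SignatureSet")) sig$genes else as.character(sig)
  missing <- setdiff(genes, rownames(z))
  if (length(missing) > 0)
    stop("signature genes missing from z-matrix: ",
         paste(missing, collapse = ", "))
  v <- unclass(z)
  colMeans(v[genes, , drop = FALSE]) - colMeans(v)
}

#' Significance of the per-group stemness gradient
#'
#' Within each group, the spread (SD) of per-cell signature scores is
#' compared to the spread obtained from size-matched random gene sets drawn
#' without replacement from the universe. The empirical p-value uses the
#' (1 + k) / (1 + n) estimator.
#'
#' @param z `ExpressionMatrix` in ZSCORE space (single cells).
#' @param sig a `SignatureSet` or gene-id vector.
#' @param grouping named group label per cell (names = cell ids) or a
#'   `SampleMetadata`.
#' @param n_random number of random sets (default 100, must be > 0).
#' @param seed RNG seed.
#' @param universe genes the random sets are drawn from (default: all rows
#'   of `z`; restrict to one biotype to match the signature's).
#' @return data.frame per group: `group`, `sd_observed`, `sd_random_mean`,
#'   `p`.
#' @export
gradient_significance <- function(z, sig, grouping, n_random = 100, seed = 1L,
                                  universe = rownames(z)) {
  if (n_random <= 0) stop("n_random must be positive")
  genes <- if (inherits(sig, "SignatureSet")) sig$genes else as.character(sig)
  if (inherits(grouping, "SampleMetadata"))
    grouping <- stats::setNames(grouping$group, grouping$sample_id)
  groups <- grouping[colnames(z)]
  if (anyNA(groups)) stop("every cell needs a group label")
  if (length(universe) < 2 * length(genes))
    warning("universe smaller than twice the signature; null sets overlap it heavily")
  obs <- signature_score(z, genes)
  set.seed(seed)
  null_sets <- lapply(seq_len(n_random), function(i)
    sample(universe, length(genes)))
  null_scores <- vapply(null_sets, function(g) signature_score(z, g),
                        numeric(ncol(z)))
  res <- lapply(unique(groups), function(g) {
    cells <- groups == g
    if (sum(cells) < 3) stop("group ", g, " has fewer than 3 cells")
    sd_obs <- stats::sd(obs[cells])
    sd_null <- apply(null_scores[cells, , drop = FALSE], 2, stats::sd)
    data.frame(group = g, sd_observed = sd_obs,
               sd_random_mean = mean(sd_null),
               p = (1 + sum(sd_null >= sd_obs)) / (1 + n_random),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Subtype scores per cell
#'
#' One [signature_score()] per classifier set.
#' @param z `ExpressionMatrix` in ZSCORE space.
#' @param classifiers named list of 4 `SignatureSet`s (or gene-id vectors),
#'   one per subtype.
#' @return cells x subtypes numeric matrix (a `ScoreTable`).
#' @export
subtype_scores <- function(z, classifiers) {
  scores <- vapply(classifiers, function(s) signature_score(z, s),
                   numeric(ncol(z)))
  rownames(scores) <- colnames(z)
  scores
}

#' Empirical subtype score cutoffs from random gene sets
#'
#' For each subtype, scores `n_random` size-matched random gene sets in
#' every cell and takes the (1 - q) quantile of the pooled null scores
#' (n_random x cells values) as the cutoff.
#'
#' @inheritParams subtype_scores
#' @param n_random random sets per subtype (default 100).
#' @param q tail probability, in (0, 0.5); default 0.01 (a 1\% cutoff).
#' @param seed RNG seed.
#' @param universe sampling universe for the random sets.
#' @return named numeric vector of per-subtype cutoffs.
#' @export
subtype_cutoffs <- function(z, classifiers, n_random = 100, q = 0.01,
                            seed = 1L, universe = rownames(z)) {
  if (q <= 0 || q >= 0.5) stop("q must lie in (0, 0.5)")
  set.seed(seed)
  vapply(classifiers, function(s) {
    genes <- if (inherits(s, "SignatureSet")) s$genes else as.character(s)
    pool <- vapply(seq_len(n_random), function(i)
      signature_score(z, sample(universe, length(genes))),
      numeric(ncol(z)))
    stats::quantile(pool, 1 - q, names = FALSE)
  }, numeric(1))
}

#' Classify cells by the subtypes whose cutoff they pass
#'
#' A cell passes a subtype when its score strictly exceeds that subtype's
#' cutoff; a cell may pass several subtypes (hybrid) or none (unclassified).
#'
#' @param scores cells x subtypes matrix from [subtype_scores()].
#' @param cutoffs named per-subtype cutoffs from [subtype_cutoffs()].
#' @return a `SubtypeCall` list: `passing` (list of passing subtype sets per
#'   cell), `n_subtypes` (named integer), `top` (named character; the
#'   top-scoring passing subtype, NA when unclassified).
#' @export
classify_cells <- function(scores, cutoffs) {
  cutoffs <- cutoffs[colnames(scores)]
  if (anyNA(cutoffs)) stop("cutoffs and scores name different subtypes")
  pass <- sweep(scores, 2, cutoffs, ">")
  passing <- apply(pass, 1, function(row) colnames(scores)[row],
                   simplify = FALSE)
  top <- vapply(rownames(scores), function(cell) {
    p <- passing[[cell]]
    if (length(p) == 0) return(NA_character_)
    p[which.max(scores[cell, p])]
  }, character(1))
  structure(list(passing = passing,
                 n_subtypes = stats::setNames(lengths(passing), rownames(scores)),
                 top = top),
            class = "SubtypeCall")
}

#' Percent agreement between two subtype classifications
#'
#' Per cell, the calls agree when the top-scoring passing subtype labels
#' match; two unclassified calls also agree. Reported as a percentage over
#' the common cell universe.
#'
#' @param a,b `SubtypeCall`s over the same cells.
#' @return percent agreement (0-100).
#' @export
classification_consistency <- function(a, b) {
  cells <- intersect(names(a$top), names(b$top))
  if (length(cells) == 0) stop("the two classifications share no cells")
  if (length(cells) != length(a$top) || length(cells) != length(b$top))
    stop("the two classifications cover different cell sets")
  same <- (is.na(a$top[cells]) & is.na(b$top[cells])) |
    (!is.na(a$top[cells]) & !is.na(b$top[cells]) &
       a$top[cells] == b$top[cells])
  100 * mean(same)
}
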