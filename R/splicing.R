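#' Within-gene relative abundances of splice variants
#'
#' For every (gene, cell) with positive gene-level TPM, each transcript's
#' relative abundance is its TPM divided by the summed TPM of the gene's
#' transcripts in that cell. Variants without expression (TPM = 0) are
#' filtered from the table, as are (gene, cell) pairs where the gene is
#' undetected.
#'
#' @param tx transcript-level `ExpressionMatrix` in TPM space.
#' @param g2t data.frame with columns `gene_id`, `transcript_id`; every
#'   transcript must map to exactly one gene.
#' @param cells optional sample ids to restrict to.
#' @return a `VariantAbundanceTable` data.frame: `gene_id`, `transcript_id`,
#'   `cell_id`, `tpm`, `rel_abund`.
#' @export
relative_abundance <- function(tx, g2t, cells = colnames(tx)) {
  if (anyDuplicated(g2t$transcript_id))
    stop("a transcript maps to more than one gene")
  present <- g2t$transcript_id %in% rownames(tx)
  if (!any(present)) stop("no mapped transcript found in the matrix")
  g2t <- g2t[present, , drop = FALSE]
  v <- unclass(tx)[g2t$transcript_id, cells, drop = FALSE]
  gene <- g2t$gene_id
  out <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    tpm <- v[, j]
    denom <- tapply(tpm, gene, sum)[gene]
    keep <- tpm > 0 & denom > 0
    if (!any(keep)) next
    out[[j]] <- data.frame(gene_id = gene[keep],
                           transcript_id = g2t$transcript_id[keep],
                           cell_id = cells[j],
                           tpm = tpm[keep],
                           rel_abund = tpm[keep] / denom[keep],
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(tab, class = c("VariantAbundanceTable", "data.frame"))
}

#' Genes with at least a minimum number of annotated variants
#' @param g2t data.frame `gene_id`, `transcript_id` (annotation map).
#' @param min_variants inclusive threshold (default 10).
#' @return character vector of gene ids, in map order.
#' @export
select_multivariant_genes <- function(g2t, min_variants = 10) {
  counts <- table(factor(g2t$gene_id, levels = unique(g2t$gene_id)))
  names(counts)[counts >= min_variants]
}

#' Dominant splice variants per gene and cell
#'
#' In a given cell, a transcript dominates its gene when its relative
#' abundance strictly exceeds `threshold`. Thresholds above 0.5 (and 0.5
#' itself, with strict exceedance) guarantee at most one dominant transcript
#' per (gene, cell).
#'
#' @param tab a `VariantAbundanceTable`.
#' @param threshold dominance threshold in (0, 1), default 0.5; values below
#'   0.5 are rejected because uniqueness would be lost.
#' @return a `DominanceSummary` list: `per_cell` (data.frame gene_id,
#'   cell_id, dominant transcript or NA), `per_gene` (data.frame gene_id,
#'   transcript_id, n_cells_dominant), `n_dominant_variants` (named vector,
#'   distinct dominant variants per gene).
#' @export
dominant_variants <- function(tab, threshold = 0.5) {
  if (threshold < 0.5 || threshold >= 1)
    stop("threshold must be in [0.5, 1) to keep dominance unique")
  dom <- tab[tab$rel_abund > threshold, , drop = FALSE]
  key <- paste(tab$gene_id, tab$cell_id)
  all_pairs <- unique(data.frame(gene_id = tab$gene_id, cell_id = tab$cell_id,
                                 stringsAsFactors = FALSE))
  dkey <- paste(dom$gene_id, dom$cell_id)
  all_pairs$dominant <- dom$transcript_id[match(paste(all_pairs$gene_id,
                                                      all_pairs$cell_id), dkey)]
  per_gene <- if (nrow(dom) > 0) {
    agg <- stats::aggregate(list(n_cells_dominant = dom$cell_id),
                            by = list(gene_id = dom$gene_id,
                                      transcript_id = dom$transcript_id),
                            FUN = length)
    agg[order(agg$gene_id, -agg$n_cells_dominant), ]
  } else {
    data.frame(gene_id = character(0), transcript_id = character(0),
               n_cells_dominant = integer(0))
  }
  genes <- unique(tab$gene_id)
  ndv <- stats::setNames(integer(length(genes)), genes)
  if (nrow(per_gene) > 0) {
    cnt <- table(per_gene$gene_id)
    ndv[names(cnt)] <- as.integer(cnt)
  }
  structure(list(per_cell = all_pairs, per_gene = per_gene,
                 n_dominant_variants = ndv),
            class = "DominanceSummary")
}

#' Detection frequency per splice variant
#'
#' How many cells express each transcript (TPM > 0), counted from the
#' abundance table. Transcripts never detected have count 0 only if listed
#' in `all_transcripts`.
#' @param tab a `VariantAbundanceTable`.
#' @param all_transcripts optional transcript universe to report zeros for.
#' @return named integer vector transcript -> number of expressing cells.
#' @export
variant_frequency <- function(tab, all_transcripts = NULL) {
  counts <- table(tab$transcript_id)
  out <- stats::setNames(as.integer(counts), names(counts))
  if (!is.null(all_transcripts)) {
    full <- stats::setNames(integer(length(all_transcripts)), all_transcripts)
    full[names(out)] <- out
    out <- full
  }
  out
}

#' Number of detected variants of one gene per cell
#' @param tab a `VariantAbundanceTable`.
#' @param gene a gene id present in the table.
#' @param cells cell universe to report (cells without the gene get 0).
#' @return named integer vector cell -> detected transcript count.
#' @export
variants_per_cell <- function(tab, gene, cells = unique(tab$cell_id)) {
  if (!gene %in% tab$gene_id) stop("gene not in table: ", gene)
  sub <- tab[tab$gene_id == gene, , drop = FALSE]
  counts <- table(sub$cell_id)
  out <- stats::setNames(integer(length(cells)), cells)
  out[names(counts)] <- as.integer(counts)
  out
}

#' Pairwise detection association between a gene's variants
#'
#' For each transcript pair of the gene, the phi coefficient of their
#' detection indicators across the cells where the gene is expressed.
#' Positive phi marks preferential co-expression, negative phi mutual
#' exclusivity. Pairs involving a transcript detected in all or none of the
#' cells (constant indicator) are NA.
#'
#' @param tab a `VariantAbundanceTable`.
#' @param gene gene id with >= 2 detected transcripts.
#' @return symmetric matrix of phi coefficients (NA on the diagonal and for
#'   constant indicators).
#' @export
variant_association <- function(tab, gene) {
  sub <- tab[tab$gene_id == gene, , drop = FALSE]
  if (nrow(sub) == 0) stop("gene not in table: ", gene)
  cells <- unique(sub$cell_id)
  txs <- unique(sub$transcript_id)
  if (length(txs) < 2) stop("gene has fewer than 2 detected transcripts")
  ind <- matrix(FALSE, length(txs), length(cells),
                dimnames = list(txs, cells))
  ind[cbind(match(sub$transcript_id, txs), match(sub$cell_id, cells))] <- TRUE
  phi <- matrix(NA_real_, length(txs), length(txs),
                dimnames = list(txs, txs))
  if (length(cells) < 3) {
    warning("gene expressed in fewer than 3 cells; associations undefined")
    return(phi)
  }
  n <- length(cells)
  for (i in seq_along(txs)) for (j in seq_along(txs)) {
    if (j <= i) next
    a <- sum(ind[i, ] & ind[j, ])
    b <- sum(ind[i, ] & !ind[j, ])
    c_ <- sum(!ind[i, ] & ind[j, ])
    d <- n - a - b - c_
    denom <- sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
    phi[i, j] <- phi[j, i] <- if (denom == 0) NA_real_ else (a * d - b * c_) / denom
  }
  phi
}
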