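#' Expression matrix with an explicit value space
#'
#' A thin S3 container for a features x samples expression matrix that keeps
#' track of which space the values live in: raw `TPM`, `LOG2_TPM1`
#' (log2(TPM+1)) or per-gene `ZSCORE`. Downstream operations check the space
#' so that, e.g., a z-score matrix is never log-transformed twice.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimnames must be set, unique and non-empty.
#' @param space one of `"TPM"`, `"LOG2_TPM1"`, `"ZSCORE"`.
#' @return an `ExpressionMatrix` object (a numeric matrix with a `space`
#'   attribute and class `ExpressionMatrix`).
#' @export
expression_matrix <- function(values, space = c("TPM", "LOG2_TPM1", "ZSCORE")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature and sample ids as dimnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (space %in% c("TPM", "LOG2_TPM1")) {
    bad <- which(values < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("negative value in %s space at feature '%s', sample '%s'",
                   space, rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  structure(values, space = space, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
#' @method print ExpressionMatrix
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              expr_space(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Value space of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return the space string.
#' @export
expr_space <- function(m) {
  s <- attr(m, "space")
  if (is.null(s)) stop("not an ExpressionMatrix: no space attribute")
  s
}

#' Subset an ExpressionMatrix, preserving class and space
#' @param m an `ExpressionMatrix`.
#' @param features,samples character vectors of ids (NULL keeps all).
#' @return the subset `ExpressionMatrix`.
#' @export
expr_subset <- function(m, features = NULL, samples = NULL) {
  v <- unclass(m)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing) > 0)
      stop("unknown feature ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing) > 0)
      stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, expr_space(m))
}

#' Sample metadata table
#'
#' @param sample_id character vector of sample ids.
#' @param group group-of-origin label per sample.
#' @param kind one of `"single_cell"`, `"population_control"`,
#'   `"gsc_culture"`, `"dgc_culture"` per sample.
#' @param pair_id optional pairing key linking a GSC culture to its matched
#'   differentiated (DGC) culture; NA elsewhere.
#' @return a `data.frame` with class `SampleMetadata`.
#' @export
sample_metadata <- function(sample_id, group, kind, pair_id = NA_character_) {
  kinds <- c("single_cell", "population_control", "gsc_culture", "dgc_culture")
  if (!all(kind %in% kinds))
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  df <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   kind = as.character(kind),
                   pair_id = as.character(pair_id),
                   stringsAsFactors = FALSE)
  # a GSC/DGC pair must come from one group
  paired <- df[!is.na(df$pair_id) & df$kind %in% c("gsc_culture", "dgc_culture"), ]
  if (nrow(paired) > 0) {
    gp <- tapply(paired$group, paired$pair_id, function(g) length(unique(g)))
    if (any(gp > 1)) stop("gsc/dgc samples sharing a pair_id must share a group")
  }
  class(df) <- c("SampleMetadata", "data.frame")
  df
}

#' Check that every sample of a matrix has a metadata row
#' @param m an `ExpressionMatrix`.
#' @param meta a `SampleMetadata` data.frame.
#' @return invisibly TRUE; stops otherwise.
#' @export
check_metadata <- function(m, meta) {
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing) > 0)
    stop("samples missing from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' Gene annotation table
#'
#' @param gene_id character vector of gene ids.
#' @param biotype `"lncRNA"` or `"protein_coding"` per gene.
#' @param transcript_ids list of character vectors, transcripts per gene;
#'   transcript ids must be unique across genes.
#' @return a `data.frame` with class `GeneAnnotation` and a list column
#'   `transcript_ids`.
#' @export
gene_annotation <- function(gene_id, biotype, transcript_ids = NULL) {
  if (!all(biotype %in% c("lncRNA", "protein_coding")))
    stop("biotype must be 'lncRNA' or 'protein_coding'")
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  if (is.null(transcript_ids))
    transcript_ids <- as.list(paste0(gene_id, ".1"))
  all_tx <- unlist(transcript_ids, use.names = FALSE)
  if (anyDuplicated(all_tx)) stop("transcript ids must be unique across genes")
  df <- data.frame(gene_id = as.character(gene_id),
                   biotype = as.character(biotype),
                   stringsAsFactors = FALSE)
  df$transcript_ids <- transcript_ids
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Long-format gene-to-transcript map from a GeneAnnotation
#' @param annot a `GeneAnnotation`.
#' @return data.frame with columns `gene_id`, `transcript_id`.
#' @export
gene_transcript_map <- function(annot) {
  n <- lengths(annot$transcript_ids)
  data.frame(gene_id = rep(annot$gene_id, n),
             transcript_id = unlist(annot$transcript_ids, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# ---- I/O ---------------------------------------------------------------

#' Write an ExpressionMatrix as TSV
#'
#' Rows are features, columns samples; the first column holds the feature id.
#' @param m an `ExpressionMatrix`.
#' @param path output file.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ExpressionMatrix from TSV
#' @param path TSV written by [write_expression_tsv()] (first column =
#'   feature id, remaining columns = samples).
#' @param space value space of the stored numbers.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, space = "TPM") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  expression_matrix(v, space)
}

#' Write an ExpressionMatrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into a directory,
#' the sparse exchange layout common for single-cell matrices.
#' @param m an `ExpressionMatrix`.
#' @param dir output directory (created if absent).
#' @export
write_expression_mtx <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- Matrix::Matrix(unclass(m), sparse = TRUE)
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read an ExpressionMatrix from an MTX triplet directory
#' @param dir directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @param space value space of the stored numbers.
#' @return an `ExpressionMatrix` (dense).
#' @export
read_expression_mtx <- function(dir, space = "TPM") {
  v <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(v) <- readLines(file.path(dir, "features.tsv"))
  colnames(v) <- readLines(file.path(dir, "barcodes.tsv"))
  expression_matrix(v, space)
}

#' Write/read sample metadata TSV
#' @param meta a `SampleMetadata`.
#' @param path file path.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "group", "kind", "pair_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("metadata TSV lacks required columns: ", paste(missing, collapse = ", "))
  df$pair_id[df$pair_id %in% c("", "NA")] <- NA_character_
  sample_metadata(df$sample_id, df$group, df$kind, df$pair_id)
}

#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member genes.
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}
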