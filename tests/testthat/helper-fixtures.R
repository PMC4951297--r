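# Shared fixtures, built in code.

# 6-gene x 9-cell LOG2_TPM1 toy exercising both gene-filter branches and
# both strict boundaries: gA passes the overall-mean branch, gC only the
# per-group branch, gB and gD sit exactly on the two thresholds, gE is
# undetected in the last two cells, gF is silent.
preproc_toy <- function() {
  cells <- paste0("c", 1:9)
  groups <- rep(c("g1", "g2", "g3"), each = 3)
  v <- rbind(
    gA = rep(2.1, 9),
    gB = rep(2.0, 9),
    gC = c(rep(4.1, 3), rep(0, 6)),
    gD = c(rep(4.0, 3), rep(0, 6)),
    gE = c(rep(5, 7), 0, 0),
    gF = rep(0, 9))
  colnames(v) <- cells
  list(m = expression_matrix(v, "LOG2_TPM1"),
       meta = sample_metadata(cells, groups, rep("single_cell", 9)))
}

# small preprocessed cohort for reuse across tests
small_cohort <- function(seed = 1, ...) {
  cfg <- sim_config(n_groups = 3, cells_per_group = 20, n_lnc = 300,
                    n_modules = 2, module_size = 20, stemness_set_size = 15,
                    subtype_sets = list(sizes = rep(10L, 4), effects = rep(2, 4)),
                    n_multivariant_genes = 5, seed = seed, ...)
  co <- generate_cohort(cfg)
  lg <- log_transform(co$expr)
  genes <- select_genes(lg, co$meta)
  cells <- select_cells(lg, genes)
  z <- zscore(expr_subset(lg, genes, cells))
  list(cfg = cfg, cohort = co, log = lg, genes = genes, cells = cells, z = z)
}

# exhaustive BMU scan, independent of the package's search
brute_bmu <- function(codebook, x) {
  d2 <- apply(codebook, 1, function(w) sum((w - x)^2))
  which.min(d2)
}

# hex adjacency on a torus, enumerated directly from the odd-row-offset
# rule: row r even -> (r, c+-1), (r-1, c-1), (r-1, c), (r+1, c-1), (r+1, c);
# row r odd -> (r, c+-1), (r-1, c), (r-1, c+1), (r+1, c), (r+1, c+1)
oracle_hex_neighbors <- function(xdim, ydim) {
  id <- function(r, c) ((r %% ydim) * xdim + (c %% xdim)) + 1
  lapply(seq_len(xdim * ydim), function(i) {
    r <- (i - 1) %/% xdim; c <- (i - 1) %% xdim
    off <- if (r %% 2 == 0)
      list(c(0, -1), c(0, 1), c(-1, -1), c(-1, 0), c(1, -1), c(1, 0))
    else
      list(c(0, -1), c(0, 1), c(-1, 0), c(-1, 1), c(1, 0), c(1, 1))
    nb <- vapply(off, function(o) id(r + o[1], c + o[2]), numeric(1))
    unique(nb[nb != i])
  })
}

demo_pipeline_config <- function(outdir, seed = 11) {
  list(seed = seed, outdir = outdir,
       simulate = list(enabled = TRUE, n_groups = 3, cells_per_group = 15,
                       n_lnc = 250, n_modules = 2, module_size = 15,
                       stemness_set_size = 12,
                       subtype_sets = list(sizes = rep(10L, 4),
                                           effects = rep(2, 4)),
                       n_multivariant_genes = 4),
       structure = list(top_n = 100, top_k_abundant = 20),
       som = list(train_n = 80, epochs = 40),
       signatures = list(n_random = 50))
}
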