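test_that("percent expressed counts strictly positive values", {
  v <- rbind(g1 = c(0, 1, 2), g2 = c(0, 3, 1), g3 = c(0, 0, 5),
             g4 = c(0, 2, 4))
  colnames(v) <- c("none", "three", "all")
  pe <- percent_expressed(expression_matrix(v, "TPM"))
  expect_equal(unname(pe), c(0, 0.75, 1))
})

test_that("pairwise correlations flag groups and handle degenerate cells", {
  set.seed(1)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  v[, 2] <- 2 * v[, 1] + 3          # r = 1 with s1
  v <- v - min(v)
  v[, 4] <- 1                        # constant cell
  meta <- sample_metadata(paste0("s", 1:4), c("A", "A", "B", "B"),
                          rep("single_cell", 4))
  expect_message(cs <- pairwise_correlations(
    expression_matrix(v, "LOG2_TPM1"), meta), "constant")
  pairs <- cs$pairs
  expect_equal(nrow(pairs), 6)       # each unordered pair once
  r12 <- pairs$r[pairs$sample_a == "s1" & pairs$sample_b == "s2"]
  expect_equal(r12, 1)
  expect_true(all(is.na(pairs$r[pairs$sample_a == "s4" | pairs$sample_b == "s4"])))
  expect_true(pairs$within_group[pairs$sample_a == "s1" & pairs$sample_b == "s2"])
  # negation about the mean gives r = -1
  w <- matrix(c(v[, 1], 2 * mean(v[, 1]) - v[, 1]), ncol = 2,
              dimnames = list(rownames(v), c("a", "b")))
  cs2 <- pairwise_correlations(
    expression_matrix(w - min(w), "LOG2_TPM1"),
    sample_metadata(c("a", "b"), c("A", "A"), rep("single_cell", 2)))
  expect_equal(cs2$pairs$r, -1)
})

test_that("group shifts raise within-group over between-group correlation", {
  sc <- small_cohort(seed = 9, group_shift_sd = 1)
  lg <- expr_subset(sc$log, features = sc$genes, samples = sc$cells)
  cs <- pairwise_correlations(lg, sc$cohort$meta)
  expect_gt(median(cs$pairs$r[cs$pairs$within_group], na.rm = TRUE),
            median(cs$pairs$r[!cs$pairs$within_group], na.rm = TRUE))
})

test_that("top-variance panel ranks by variance with stable ties", {
  v <- rbind(flat = rep(1, 4), wild = c(0, 9, 0, 9), mid = c(1, 2, 3, 4))
  colnames(v) <- paste0("s", 1:4)
  m <- expression_matrix(v, "LOG2_TPM1")
  expect_identical(top_variance_genes(m, 1), "wild")
  expect_identical(sort(top_variance_genes(m, 3)), sort(rownames(v)))
  expect_error(top_variance_genes(m, 4), "exceeds")
})

test_that("PCA separates planted clusters and is rotation invariant", {
  set.seed(42)
  n <- 30
  base <- matrix(rnorm(20 * 2 * n, sd = 0.5), 20, 2 * n)
  base[1:5, seq_len(n)] <- base[1:5, seq_len(n)] + 4   # planted shift
  dimnames(base) <- list(paste0("g", 1:20), paste0("s", 1:(2 * n)))
  m <- expression_matrix(base - min(base), "LOG2_TPM1")
  p <- run_pca(m)
  pc1 <- p$coords[, 1]
  gap <- abs(mean(pc1[seq_len(n)]) - mean(pc1[-seq_len(n)]))
  wsd <- max(sd(pc1[seq_len(n)]), sd(pc1[-seq_len(n)]))
  expect_gt(gap, 3 * wsd)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1)
  # orthogonal rotation of the gene space leaves variance fractions alone
  q <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
  rot <- t(q) %*% (base - min(base))
  dimnames(rot) <- dimnames(base)
  p2 <- run_pca(expression_matrix(rot - min(rot), "LOG2_TPM1"))
  expect_equal(p2$var_explained, p$var_explained, tolerance = 1e-8)
})

test_that("abundance union panels behave on identical, disjoint and toy controls", {
  v <- matrix(0, 6, 3, dimnames = list(paste0("g", 1:6), paste0("ctl", 1:3)))
  v[, 1] <- c(9, 8, 1, 1, 1, 0)   # top-2: g1 g2
  v[, 2] <- c(0, 8, 9, 1, 1, 1)   # top-2: g3 g2
  v[, 3] <- c(0, 0, 1, 1, 9, 8)   # top-2: g5 g6
  m <- expression_matrix(v, "LOG2_TPM1")
  expect_identical(top_abundant_union(m, 2), c("g1", "g2", "g3", "g5", "g6"))
  colnames_same <- paste0("c", 1:3)
  same <- expression_matrix(matrix(v[, 1], 6, 3,
                                   dimnames = list(rownames(v), colnames_same)),
                            "LOG2_TPM1")
  expect_length(top_abundant_union(same, 2), 2)
  expect_error(top_abundant_union(m, 7), "exceeds")
})

test_that("hierarchical clustering matches hand agglomeration and is sane", {
  # 1-D points 0, 1, 5, 7: average linkage merges at heights 1, 2, 5.5
  v <- matrix(c(0, 1, 5, 7), 4, 2,
              dimnames = list(paste0("p", 1:4), c("a", "b")))
  v[, 2] <- 0
  hc <- hier_cluster(expression_matrix(v, "LOG2_TPM1"),
                     linkage = "average", distance = "euclidean")
  expect_equal(sort(hc$row_hclust$height), c(1, 2, 5.5))
  # identical rows merge first at height 0
  w <- rbind(p1 = c(1, 2, 3), p2 = c(1, 2, 3), p3 = c(9, 1, 4))
  colnames(w) <- paste0("s", 1:3)
  hc2 <- hier_cluster(expression_matrix(w, "LOG2_TPM1"),
                      distance = "euclidean")
  expect_equal(min(hc2$row_hclust$height), 0)
  expect_error(hier_cluster(expression_matrix(
    matrix(c(1, NaN, 2, 3), 2, dimnames = list(c("a", "b"), c("x", "y"))),
    "ZSCORE")), "non-finite")
  # permuting rows preserves the tree (cophenetic distances)
  set.seed(3)
  r <- matrix(runif(24), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  m1 <- expression_matrix(r, "LOG2_TPM1")
  perm <- sample(6)
  m2 <- expression_matrix(r[perm, ], "LOG2_TPM1")
  c1 <- as.matrix(stats::cophenetic(hier_cluster(m1, distance = "euclidean")$row_hclust))
  c2 <- as.matrix(stats::cophenetic(hier_cluster(m2, distance = "euclidean")$row_hclust))
  expect_equal(c2[rownames(c1), colnames(c1)], c1)
  # newick export parses back with the same tips
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(hier_cluster(m1, distance = "euclidean")$row_hclust, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(r))
})
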