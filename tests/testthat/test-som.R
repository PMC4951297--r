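test_that("grid sizing follows the 5*sqrt(N) heuristic", {
  gs <- som_grid_size(2003)
  expect_equal(gs[["xdim"]] * gs[["ydim"]], 225)  # M = round(223.77) = 224
  expect_lte(abs(gs[["xdim"]] * gs[["ydim"]] - 224) / 224, 0.1)
  gs100 <- som_grid_size(100)                      # M = 50
  expect_lte(abs(prod(gs100) - 50) / 50, 0.1)
  gs4 <- som_grid_size(4)                          # M = 10
  expect_lte(abs(prod(gs4) - 10) / 10, 0.1)
  expect_error(som_grid_size(3), "at least 4")
})

test_that("toroidal lattice distances are symmetric and wrap shortens them", {
  g <- som_grid(6, 6)
  d <- g$unit_dist
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # opposite-edge units: planar distance 5, toroidal distance 1
  u_left <- 1                 # (row 0, col 0)
  u_right <- 6                # (row 0, col 5)
  planar <- sqrt(sum((g$pos[u_left, ] - g$pos[u_right, ])^2))
  expect_equal(d[u_left, u_right], 1)
  expect_lt(d[u_left, u_right], planar)
  # triangle inequality on a sample of triples
  set.seed(1)
  for (i in 1:50) {
    t3 <- sample(36, 3)
    expect_lte(d[t3[1], t3[3]], d[t3[1], t3[2]] + d[t3[2], t3[3]] + 1e-12)
  }
  # every unit has 6 hex neighbors at lattice distance 1
  expect_true(all(lengths(g$neighbors) == 6))
  expect_true(all(vapply(seq_len(36), function(i)
    all(abs(d[i, g$neighbors[[i]]] - 1) < 1e-9), logical(1))))
})

test_that("PC initialization spans the data mean and top components", {
  set.seed(2)
  x <- matrix(rnorm(200 * 30), 200, 30)
  g <- som_grid(5, 4)
  g0 <- som_init(g, x, n_pcs = 0)
  expect_true(all(abs(sweep(g0$codebook, 2, colMeans(x))) < 1e-12))

  g10 <- som_init(g, x, n_pcs = 10, seed = 1)
  p <- prcomp(x)
  centered <- sweep(g10$codebook, 2, colMeans(x))
  resid <- centered - centered %*% p$rotation[, 1:10] %*% t(p$rotation[, 1:10])
  expect_lt(max(abs(resid)), 1e-8)
  g10b <- som_init(g, x, n_pcs = 10, seed = 2)
  expect_false(identical(g10$codebook, g10b$codebook))
  centered_b <- sweep(g10b$codebook, 2, colMeans(x))
  resid_b <- centered_b - centered_b %*% p$rotation[, 1:10] %*% t(p$rotation[, 1:10])
  expect_lt(max(abs(resid_b)), 1e-8)
})

test_that("training converges to a single vector and respects alpha = 0", {
  set.seed(3)
  x <- matrix(rnorm(8), 1, 8)
  g <- som_grid(4, 4)
  g <- som_init(g, matrix(rnorm(80), 10, 8), n_pcs = 2, seed = 1)
  init_cb <- g$codebook
  trained <- som_train(g, x, epochs = 200, seed = 1)
  hit <- som_map(trained, x)
  expect_lt(hit$qe, 1e-2)
  frozen <- som_train(g, x, epochs = 10, alpha = c(0, 0), seed = 1)
  expect_equal(frozen$codebook, init_cb)
  expect_error(som_train(g, matrix(c(1, NaN), 1, 2)[, rep(1:2, 4)],
                         epochs = 1), "non-finite|dimension")
})

test_that("training is deterministic and reduces quantization error", {
  # quantization error declines at the scale the map is meant to run at:
  # a few hundred training genes on a grid sized by the 5*sqrt(N) heuristic
  sc <- small_cohort(seed = 14)
  z <- unclass(sc$z)
  tg <- top_variance_genes(sc$z, 100)
  dims <- som_grid_size(length(tg))
  g <- som_init(som_grid(dims[1], dims[2]), z[tg, ], seed = 14)
  tr <- som_train(g, z[tg, ], epochs = 100, seed = 14)
  expect_lte(tr$epoch_qe[100], tr$epoch_qe[1])
  set.seed(1)
  x <- matrix(rnorm(40 * 6), 40, 6)
  g <- som_init(som_grid(4, 4), x, n_pcs = 3, seed = 7)
  t1 <- som_train(g, x, epochs = 20, seed = 7)
  t2 <- som_train(g, x, epochs = 20, seed = 7)
  expect_identical(t1$codebook, t2$codebook)
})

test_that("BMU mapping handles exact matches, duplicates and ties", {
  set.seed(4)
  g <- som_init(som_grid(4, 4), matrix(rnorm(160), 20, 8), n_pcs = 3, seed = 1)
  x <- rbind(unit5 = g$codebook[5, ], dup1 = rnorm(8))
  x <- rbind(x, dup2 = x["dup1", ])
  mp <- som_map(g, x)
  expect_equal(mp$unit[1], 5)
  expect_equal(mp$qe[1], 0)
  expect_equal(mp$unit[2], mp$unit[3])
  expect_error(som_map(g, matrix(0, 1, 3)), "dimension")
})

test_that("u-matrix is zero for constant codebooks and translation invariant", {
  g <- som_grid(4, 4)
  g$codebook <- matrix(1, 16, 3)
  expect_equal(compute_umatrix(g), rep(0, 16))
  # translating the lattice contents by one column leaves the value multiset
  set.seed(5)
  g$codebook <- matrix(rnorm(48), 16, 3)
  u <- compute_umatrix(g)
  shift <- function(i) {
    r <- (i - 1) %/% 4; c <- (i - 1) %% 4
    r * 4 + ((c + 1) %% 4) + 1
  }
  g2 <- g
  g2$codebook[vapply(1:16, shift, numeric(1)), ] <- g$codebook
  u2 <- compute_umatrix(g2)
  expect_equal(u2[vapply(1:16, shift, numeric(1))], u)
})

test_that("u-matrix agrees with an independently enumerated neighbor oracle", {
  g <- som_grid(3, 3)
  set.seed(6)
  g$codebook <- matrix(rnorm(18), 9, 2)
  nb <- oracle_hex_neighbors(3, 3)
  expected <- vapply(1:9, function(i)
    mean(vapply(nb[[i]], function(j)
      sqrt(sum((g$codebook[i, ] - g$codebook[j, ])^2)), numeric(1))),
    numeric(1))
  expect_equal(compute_umatrix(g), expected)
  # single-outlier shape: the outlier carries the largest u-value
  g$codebook <- matrix(0, 9, 1)
  g$codebook[5, ] <- 1
  u <- compute_umatrix(g)
  expect_equal(which.max(u), 5)
  expect_true(all(u[nb[[5]]] > 0))
})

test_that("u-matrix clustering partitions units and recovers planted blobs", {
  g <- som_grid(4, 4)
  g$codebook <- matrix(0, 16, 2)
  expect_warning(cl0 <- som_cluster_units(g, compute_umatrix(g)),
                 "one cluster")
  expect_equal(cl0$unit_cluster, rep(1L, 16))

  blob1 <- c(1, 2, 5, 6); blob2 <- c(11, 12, 15, 16)
  cb <- g$pos
  cb[blob1, ] <- matrix(colMeans(g$pos[blob1, ]), 4, 2, byrow = TRUE)
  cb[blob2, ] <- matrix(colMeans(g$pos[blob2, ]), 4, 2, byrow = TRUE)
  g$codebook <- cb
  cl <- som_cluster_units(g, compute_umatrix(g))
  expect_length(cl$seeds, 2)
  expect_length(unique(cl$unit_cluster[blob1]), 1)
  expect_length(unique(cl$unit_cluster[blob2]), 1)
  expect_false(cl$unit_cluster[1] == cl$unit_cluster[11])
  # partition: every unit in exactly one cluster, cluster count = seed count
  expect_true(all(cl$unit_cluster %in% seq_along(cl$seeds)))
})

test_that("cell components average mapped gene z-scores per unit", {
  colnames_z <- c("cell1", "cell2")
  z <- expression_matrix(
    matrix(c(1, 2, 3, -1, 0, 0, 0, 5), 4, 2,
           dimnames = list(c("gA", "gB", "gC", "gD"), colnames_z)),
    "ZSCORE")
  mapping <- structure(data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                                  unit = c(2L, 2L, 2L, 4L), qe = 0),
                       class = c("SOMMapping", "data.frame"))
  comp <- cell_component(mapping, z, "cell1", n_units = 5)
  expect_equal(comp, c(NA, 2, NA, -1, NA))
  comp2 <- cell_component(mapping, z, "cell2", n_units = 5)
  expect_equal(comp2, c(NA, 0, NA, 5, NA))
  expect_error(cell_component(mapping, z, "nope"), "unknown cell")
})

test_that("cluster enrichment matches exact hypergeometric counts", {
  universe <- paste0("g", 1:100)
  set5 <- paste0("g", 1:5)
  sets <- list(HIT = set5, MISS = paste0("g", 50:60))
  res <- enrich_cluster(set5, sets, universe)
  expect_equal(res$p[res$set == "HIT"], 1 / choose(100, 5))
  expect_equal(res$p[res$set == "MISS"], 1)          # zero overlap
  single <- enrich_cluster(set5, sets["HIT"], universe)
  expect_equal(single$q, single$p)                   # BH of one test
  expect_error(enrich_cluster(set5, sets, character(0)), "universe")
  expect_error(enrich_cluster(c("gX"), sets, universe), "outside")
})

test_that("genes from one coexpression module map close together", {
  sc <- small_cohort(seed = 12, module_shift = 1.5)
  z <- unclass(sc$z)
  tg <- top_variance_genes(sc$z, 150)
  gdim <- som_grid_size(length(tg))
  g <- som_init(som_grid(gdim[1], gdim[2]), z[tg, ], seed = 12)
  g <- som_train(g, z[tg, ], epochs = 60, seed = 12)
  mp <- som_map(g, z)
  mm <- sc$cohort$truth$module_membership
  mods <- split(names(mm)[!is.na(mm)], mm[!is.na(mm)])
  tt <- module_topology_test(g, mp, mods, n_perm = 199, seed = 12)
  expect_lt(tt$p, 0.05)
  expect_lt(tt$observed, mean(tt$null))
})
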