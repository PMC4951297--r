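#' Heuristic SOM grid sizing
#'
#' Total map units M = round(5 * sqrt(N)) for N training genes, split into a
#' near-square lattice: xdim = round(sqrt(M)), ydim = round(M / xdim).
#' @param n_genes number of training vectors (>= 4).
#' @return integer vector `c(xdim, ydim)`.
#' @export
som_grid_size <- function(n_genes) {
  if (n_genes < 4) stop("need at least 4 training genes")
  m <- round(5 * sqrt(n_genes))
  xdim <- round(sqrt(m))
  ydim <- round(m / xdim)
  c(xdim = as.integer(xdim), ydim = as.integer(ydim))
}

#' Construct a toroidal hexagonal SOM lattice
#'
#' Units live on a hexagonal lattice with odd rows offset by half a unit;
#' planar coordinates are `x = col + 0.5 * (row %% 2)`,
#' `y = row * sqrt(3) / 2`. Opposite edges wrap (toroidal), and lattice
#' distances are the minimum planar distance over the nine torus images.
#'
#' @param xdim,ydim lattice dimensions (columns, rows).
#' @return a `SOMGrid` list: `xdim`, `ydim`, `toroidal`, `pos` (M x 2 planar
#'   unit coordinates), `unit_dist` (M x M toroidal lattice distances),
#'   `neighbors` (list of 6 neighbor indices per unit), `codebook` (NULL
#'   until initialized).
#' @export
som_grid <- function(xdim, ydim) {
  stopifnot(xdim >= 1, ydim >= 1)
  m <- xdim * ydim
  row <- (seq_len(m) - 1) %/% xdim
  col <- (seq_len(m) - 1) %% xdim
  pos <- cbind(x = col + 0.5 * (row %% 2), y = row * sqrt(3) / 2)
  grid <- list(xdim = as.integer(xdim), ydim = as.integer(ydim),
               toroidal = TRUE, pos = pos, codebook = NULL)
  grid$unit_dist <- torus_unit_distances(grid)
  grid$neighbors <- hex_neighbors(xdim, ydim)
  class(grid) <- "SOMGrid"
  grid
}

#' @export
#' @method print SOMGrid
print.SOMGrid <- function(x, ...) {
  cat(sprintf("SOMGrid: %d x %d toroidal hexagonal lattice (%d units), %s\n",
              x$xdim, x$ydim, x$xdim * x$ydim,
              if (is.null(x$codebook)) "uninitialized"
              else sprintf("codebook dim %d", ncol(x$codebook))))
  invisible(x)
}

# minimum planar distance over the 9 torus images
torus_unit_distances <- function(grid) {
  wx <- grid$xdim
  wy <- grid$ydim * sqrt(3) / 2
  x <- grid$pos[, 1]; y <- grid$pos[, 2]
  dmin <- NULL
  for (kx in -1:1) for (ky in -1:1) {
    dx <- outer(x, x + kx * wx, "-")
    dy <- outer(y, y + ky * wy, "-")
    d <- sqrt(dx^2 + dy^2)
    dmin <- if (is.null(dmin)) d else pmin(dmin, d)
  }
  # exact symmetry despite floating-point asymmetries in outer()
  (dmin + t(dmin)) / 2
}

# 6 hex neighbors per unit via odd-row offset arithmetic with modular wrap
hex_neighbors <- function(xdim, ydim) {
  m <- xdim * ydim
  idx <- function(r, c) (r %% ydim) * xdim + (c %% xdim) + 1L
  lapply(seq_len(m), function(i) {
    r <- (i - 1) %/% xdim
    c <- (i - 1) %% xdim
    if (r %% 2 == 0) {
      nb <- c(idx(r, c - 1), idx(r, c + 1),
              idx(r - 1, c - 1), idx(r - 1, c),
              idx(r + 1, c - 1), idx(r + 1, c))
    } else {
      nb <- c(idx(r, c - 1), idx(r, c + 1),
              idx(r - 1, c), idx(r - 1, c + 1),
              idx(r + 1, c), idx(r + 1, c + 1))
    }
    unique(nb[nb != i])
  })
}

#' Initialize SOM codebooks from principal components
#'
#' Codebooks are placed in the affine span of the data mean and the top
#' `n_pcs` principal components of the training vectors: the lattice columns
#' span PC1 and the rows PC2, each over +/- 2 sd of the component scores;
#' coordinates on the remaining components are drawn from a seeded
#' small-variance normal (sd = component sd / 10).
#'
#' @param grid a [som_grid()].
#' @param training numeric matrix of training vectors (genes x cells),
#'   typically z-scores.
#' @param n_pcs number of principal components (default 10; 0 places every
#'   codebook at the data mean).
#' @param seed RNG seed for the minor-component coordinates.
#' @return the grid with a filled `codebook` (units x cells).
#' @export
som_init <- function(grid, training, n_pcs = 10, seed = 1L) {
  training <- as.matrix(training)
  m <- grid$xdim * grid$ydim
  center <- colMeans(training)
  if (n_pcs == 0) {
    grid$codebook <- matrix(center, m, ncol(training), byrow = TRUE)
    colnames(grid$codebook) <- colnames(training)
    return(grid)
  }
  n_pcs <- min(n_pcs, nrow(training) - 1, ncol(training))
  p <- tryCatch(stats::prcomp(training, center = TRUE, scale. = FALSE),
                error = function(e) NULL)
  if (is.null(p) || all(p$sdev[seq_len(n_pcs)] < 1e-12)) {
    message("degenerate covariance; falling back to random codebook sampling")
    set.seed(seed)
    grid$codebook <- training[sample.int(nrow(training), m, replace = TRUE), ,
                              drop = FALSE]
    rownames(grid$codebook) <- NULL
    return(grid)
  }
  row <- (seq_len(m) - 1) %/% grid$xdim
  col <- (seq_len(m) - 1) %% grid$xdim
  axis <- function(i, n) if (n > 1) seq(-2, 2, length.out = n)[i + 1] else 0
  scores <- matrix(0, m, n_pcs)
  scores[, 1] <- axis(col, grid$xdim) * p$sdev[1]
  if (n_pcs >= 2) scores[, 2] <- axis(row, grid$ydim) * p$sdev[2]
  if (n_pcs >= 3) {
    set.seed(seed)
    for (j in 3:n_pcs)
      scores[, j] <- stats::rnorm(m, 0, p$sdev[j] / 10)
  }
  cb <- scores %*% t(p$rotation[, seq_len(n_pcs), drop = FALSE])
  grid$codebook <- sweep(cb, 2, center, "+")
  colnames(grid$codebook) <- colnames(training)
  grid
}

#' Train a SOM by sequential (online) updates
#'
#' Per presentation: the best-matching unit (BMU) is found by Euclidean
#' distance (ties broken by lowest unit index) and all units within the
#' current radius on the toroidal lattice move toward the vector by
#' `w <- w + alpha * (x - w)` (bubble neighborhood). Learning rate and
#' radius are interpolated linearly over the total number of updates
#' (epochs x vectors); the presentation order is reshuffled each epoch with
#' the seeded generator. The initial radius defaults to `d`, the 2/3
#' quantile of all pairwise unit-to-unit toroidal distances, declining to 2.
#'
#' @param grid an initialized [som_grid()].
#' @param training numeric matrix of training vectors (genes x cells).
#' @param epochs training epochs (default 200).
#' @param alpha length-2 learning-rate schedule, start and end (default
#'   0.05 to 0.01).
#' @param radius length-2 radius schedule; NA for the start means "auto"
#'   (the 2/3 distance quantile d). Default `c(NA, 2)`.
#' @param neighborhood `"bubble"` (full alpha within radius) or
#'   `"gaussian"`.
#' @param seed RNG seed for the per-epoch shuffles.
#' @return the grid with trained `codebook` and an `epoch_qe` element, the
#'   per-epoch mean quantization error.
#' @export
som_train <- function(grid, training, epochs = 200, alpha = c(0.05, 0.01),
                      radius = c(NA, 2), neighborhood = c("bubble", "gaussian"),
                      seed = 1L) {
  neighborhood <- match.arg(neighborhood)
  training <- as.matrix(training)
  if (is.null(grid$codebook)) stop("grid not initialized; call som_init()")
  if (ncol(training) != ncol(grid$codebook))
    stop("training vector dimension does not match codebook")
  if (any(!is.finite(training))) stop("training vectors contain non-finite values")
  n <- nrow(training)
  if (n < 1) stop("need at least 1 training vector")
  total <- epochs * n
  d0 <- if (is.na(radius[1]))
    stats::quantile(grid$unit_dist[upper.tri(grid$unit_dist)], 2 / 3,
                    names = FALSE)
  else radius[1]
  alphas <- seq(alpha[1], alpha[2], length.out = total)
  radii <- seq(d0, radius[2], length.out = total)
  set.seed(seed)
  ord <- unlist(lapply(seq_len(epochs), function(e) sample.int(n))) - 1L
  fit <- som_train_cpp(grid$codebook, training, ord, alphas, radii,
                       grid$unit_dist, as.integer(epochs),
                       neighborhood == "gaussian")
  grid$codebook <- fit$codebook
  colnames(grid$codebook) <- colnames(training)
  grid$epoch_qe <- fit$epoch_qe
  grid$radius_start <- d0
  grid
}

#' Map gene vectors to their best-matching units
#'
#' @param grid a trained [som_grid()].
#' @param vectors numeric matrix (genes x cells), same dimension as the
#'   codebook.
#' @return a `SOMMapping` data.frame: `gene_id`, `unit` (1-based BMU index),
#'   `qe` (Euclidean quantization error).
#' @export
som_map <- function(grid, vectors) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != ncol(grid$codebook))
    stop("vector dimension does not match codebook")
  hit <- som_bmu_cpp(grid$codebook, vectors)
  if (is.null(rownames(vectors)))
    rownames(vectors) <- paste0("v", seq_len(nrow(vectors)))
  structure(data.frame(gene_id = rownames(vectors), unit = hit$bmu,
                       qe = hit$qe, stringsAsFactors = FALSE),
            class = c("SOMMapping", "data.frame"))
}

#' U-matrix of a trained SOM
#'
#' Per unit, the mean Euclidean distance from its codebook to the codebooks
#' of its six lattice neighbors. Valleys (low values) mark clusters.
#' @param grid a trained [som_grid()].
#' @return numeric vector of length xdim * ydim.
#' @export
compute_umatrix <- function(grid) {
  cb <- grid$codebook
  vapply(seq_along(grid$neighbors), function(i) {
    nb <- grid$neighbors[[i]]
    mean(sqrt(rowSums((cb[nb, , drop = FALSE] -
                         matrix(cb[i, ], length(nb), ncol(cb), byrow = TRUE))^2)))
  }, numeric(1))
}

#' Cluster SOM units from u-matrix minima
#'
#' Seeds are u-matrix local minima: units strictly below all six neighbors.
#' A connected plateau of equal u-values that jointly lies below all of its
#' outside neighbors yields a single seed, its lowest-index unit. Every
#' other unit joins the cluster of the seed with the smallest codebook
#' Euclidean distance (ties broken by lowest seed index). A constant
#' u-matrix yields a single cluster with a warning.
#'
#' @param grid a trained [som_grid()].
#' @param u u-matrix from [compute_umatrix()].
#' @return a `ClusterAssignment` list: `unit_cluster` (integer per unit),
#'   `seeds` (seed unit indices, one per cluster).
#' @export
som_cluster_units <- function(grid, u) {
  m <- length(u)
  nbs <- grid$neighbors
  # candidate units: u <= every neighbor
  cand <- vapply(seq_len(m), function(i) all(u[i] <= u[nbs[[i]]]), logical(1))
  # connected components of candidates linked by equal-u adjacency
  comp <- rep(NA_integer_, m)
  nc <- 0L
  for (i in which(cand)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      eq <- nbs[[j]][cand[nbs[[j]]] & u[nbs[[j]]] == u[j]]
      new <- eq[is.na(comp[eq])]
      comp[new] <- nc
      queue <- c(queue, new)
    }
  }
  seeds <- integer(0)
  if (nc > 0) {
    for (k in seq_len(nc)) {
      members <- which(comp == k)
      if (length(members) == m) next  # constant u: no meaningful minimum
      outside <- setdiff(unique(unlist(nbs[members])), members)
      if (length(outside) == 0 ||
          all(u[outside] > max(u[members])))  # joint minimum
        seeds <- c(seeds, min(members))
    }
  }
  seeds <- sort(seeds)
  if (length(seeds) == 0) {
    warning("no u-matrix local minimum; assigning all units to one cluster")
    return(structure(list(unit_cluster = rep(1L, m), seeds = integer(0)),
                     class = "ClusterAssignment"))
  }
  cb <- grid$codebook
  d2seed <- vapply(seeds, function(s)
    rowSums((cb - matrix(cb[s, ], m, ncol(cb), byrow = TRUE))^2), numeric(m))
  d2seed <- matrix(d2seed, nrow = m)
  unit_cluster <- max.col(-d2seed, ties.method = "first")
  structure(list(unit_cluster = as.integer(unit_cluster), seeds = seeds),
            class = "ClusterAssignment")
}

#' Gene-level cluster labels from a mapping and a unit clustering
#' @param mapping a `SOMMapping` from [som_map()].
#' @param assignment a `ClusterAssignment` from [som_cluster_units()].
#' @return named integer vector gene -> cluster id.
#' @export
som_gene_clusters <- function(mapping, assignment) {
  stats::setNames(assignment$unit_cluster[mapping$unit], mapping$gene_id)
}

#' Per-cell SOM component portrait
#'
#' The value of each lattice unit is the mean z-score, in the given cell, of
#' the genes whose BMU is that unit; units with no mapped gene are NA.
#'
#' @param mapping a `SOMMapping` covering the z-matrix genes.
#' @param z `ExpressionMatrix` in ZSCORE space.
#' @param cell a sample id present in `z`.
#' @param n_units number of lattice units (defaults to the maximum mapped
#'   unit; pass `grid$xdim * grid$ydim` to force the full lattice).
#' @return numeric vector of per-unit mean z-scores (NA where empty).
#' @export
cell_component <- function(mapping, z, cell, n_units = max(mapping$unit)) {
  if (!cell %in% colnames(z)) stop("unknown cell id: ", cell)
  common <- intersect(mapping$gene_id, rownames(z))
  zz <- unclass(z)[common, cell]
  unit <- mapping$unit[match(common, mapping$gene_id)]
  out <- rep(NA_real_, n_units)
  agg <- tapply(zz, unit, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Hypergeometric over-representation of a cluster in gene sets
#'
#' One-sided hypergeometric tail P(X >= k) for the overlap k between the
#' cluster and each gene set (both intersected with the universe), with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param cluster_genes character vector, subset of `universe`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe the analysis gene universe.
#' @return data.frame: set, overlap, set_size, p, q (BH), ordered by p.
#' @export
enrich_cluster <- function(cluster_genes, gene_sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (length(gene_sets) == 0) stop("empty gene-set collection")
  extra <- setdiff(cluster_genes, universe)
  if (length(extra) > 0)
    stop("cluster genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  n_u <- length(universe)
  n_c <- length(cluster_genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(cluster_genes, set))
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_c,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Permutation test of SOM topology preservation for gene modules
#'
#' Tests whether genes planted in the same coexpression modules map closer
#' together on the lattice than random size-matched gene sets. The statistic
#' is the mean over modules of the mean pairwise toroidal BMU distance;
#' the null redraws each module from the mapped genes.
#'
#' @param grid a trained [som_grid()].
#' @param mapping a `SOMMapping`.
#' @param modules list of gene-id vectors.
#' @param n_perm permutations (default 499).
#' @param seed RNG seed.
#' @return list: `observed`, `null` (vector), `p` (one-sided, smaller =
#'   tighter than random, estimator (1 + #\{null <= obs\}) / (1 + n_perm)).
#' @export
module_topology_test <- function(grid, mapping, modules, n_perm = 499,
                                 seed = 1L) {
  unit_of <- stats::setNames(mapping$unit, mapping$gene_id)
  ud <- grid$unit_dist
  mean_pair_dist <- function(units) {
    if (length(units) < 2) return(NA_real_)
    sub <- ud[units, units]
    mean(sub[upper.tri(sub)])
  }
  stat <- function(sets) mean(vapply(sets, function(g)
    mean_pair_dist(unit_of[g]), numeric(1)))
  modules <- lapply(modules, intersect, y = mapping$gene_id)
  observed <- stat(modules)
  sizes <- lengths(modules)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    stat(lapply(sizes, function(k) sample(mapping$gene_id, k)))
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null <= observed)) / (1 + n_perm))
}

#' Draw a SOM component as a hexagon map
#'
#' Base-graphics rendering of per-unit values on the hexagonal lattice
#' (e.g. a u-matrix or a [cell_component()] portrait).
#' @param grid a [som_grid()].
#' @param values per-unit numeric vector (NA units are left blank).
#' @param main plot title.
#' @param palette color ramp function (default blue-white-red).
#' @export
plot_som_component <- function(grid, values, main = "",
                               palette = grDevices::colorRampPalette(
                                 c("#2166AC", "white", "#B2182B"))) {
  stopifnot(length(values) == nrow(grid$pos))
  cols <- rep(NA_character_, length(values))
  ok <- is.finite(values)
  if (any(ok)) {
    rng <- range(values[ok])
    idx <- if (diff(rng) == 0) rep(50L, sum(ok))
    else as.integer(1 + 99 * (values[ok] - rng[1]) / diff(rng))
    cols[ok] <- palette(100)[idx]
  }
  graphics::plot(grid$pos, type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  r <- 0.5 / cos(pi / 6)
  ang <- pi / 6 + (0:5) * pi / 3
  for (i in seq_len(nrow(grid$pos))) {
    graphics::polygon(grid$pos[i, 1] + r * cos(ang),
                      grid$pos[i, 2] + r * sin(ang),
                      col = if (is.na(cols[i])) "grey90" else cols[i],
                      border = "grey40")
  }
  invisible(NULL)
}
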