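pop_toy <- function(vals_gsc, vals_dgc, genes = paste0("g", seq_len(nrow(vals_gsc)))) {
  pairs <- ncol(vals_gsc)
  ids <- c(paste0("p", 1:pairs, "_GSC"), paste0("p", 1:pairs, "_DGC"))
  v <- cbind(vals_gsc, vals_dgc)
  dimnames(v) <- list(genes, ids)
  meta <- sample_metadata(ids, rep(paste0("T", 1:pairs), 2),
                          rep(c("gsc_culture", "dgc_culture"), each = pairs),
                          rep(paste0("T", 1:pairs), 2))
  list(m = expression_matrix(v, "LOG2_TPM1"), meta = meta)
}

test_that("paired signature derivation handles flat and degenerate genes", {
  gsc <- rbind(flat = c(3, 3, 3), up = c(5, 6, 7), const_up = c(4, 5, 6),
               down = c(1, 2, 3))
  dgc <- rbind(flat = c(3, 3, 3), up = c(2.2, 3.1, 3.9), const_up = c(3, 4, 5),
               down = c(4, 5, 6))
  toy <- pop_toy(gsc, dgc, genes = rownames(gsc))
  sig <- derive_stemness_signature(toy$m, toy$meta)
  expect_false("flat" %in% sig$genes)        # zero difference everywhere
  expect_true("const_up" %in% sig$genes)     # sd = 0, positive: p -> 0
  expect_equal(sig$stats$p[sig$stats$gene_id == "const_up"], 0)
  expect_true(sig$stats$degenerate[sig$stats$gene_id == "const_up"])
  expect_false("down" %in% sig$genes)        # significant but wrong direction
  expect_true("up" %in% sig$genes)
  one_pair <- pop_toy(gsc[, 1, drop = FALSE], dgc[, 1, drop = FALSE],
                      genes = rownames(gsc))
  expect_error(derive_stemness_signature(one_pair$m, one_pair$meta),
               "2 GSC/DGC pairs")
})

test_that("planted signatures are recovered with bounded false positives", {
  for (s in 1:3) {
    co <- generate_cohort(sim_config(seed = s))
    pp <- generate_population_pairs(co)
    sig <- derive_stemness_signature(log_transform(pp$expr), pp$meta)
    planted <- co$truth$signature_genes
    expect_gte(mean(planted %in% sig$genes), 0.9)
    expect_lte(length(setdiff(sig$genes, planted)),
               0.05 * (nrow(co$expr) - length(planted)) * 2)
  }
})

test_that("signature scores subtract the universe mean", {
  v <- matrix(c(1, 2, 3, 4, 0, 0, 0, 0), 4, 2,
              dimnames = list(paste0("g", 1:4), c("cellA", "cellB")))
  z <- expression_matrix(v, "ZSCORE")
  sc <- signature_score(z, c("g1", "g2"))
  expect_equal(unname(sc), c(mean(c(1, 2)) - mean(1:4), 0))
  expect_equal(unname(signature_score(z, rownames(v))), c(0, 0))
  expect_error(signature_score(z, c("g1", "gX")), "gX")
  # invariance to a per-cell constant shift
  shifted <- expression_matrix(sweep(v, 2, c(5, -2), "+"), "ZSCORE")
  expect_equal(signature_score(shifted, c("g1", "g2")), sc)
})

test_that("gradient significance flags planted gradients and guards inputs", {
  sc <- small_cohort(seed = 21)
  planted <- intersect(sc$cohort$truth$signature_genes, rownames(sc$z))
  grp <- setNames(sc$cohort$meta$group, sc$cohort$meta$sample_id)
  gr <- gradient_significance(sc$z, planted, grp, n_random = 100, seed = 2)
  expect_true(all(gr$p <= 0.05))
  expect_true(all(gr$sd_observed > gr$sd_random_mean))
  expect_error(gradient_significance(sc$z, planted, grp, n_random = 0),
               "positive")
  expect_warning(
    gradient_significance(sc$z, rownames(sc$z)[1:100], grp,
                          n_random = 5, seed = 1,
                          universe = rownames(sc$z)[1:150]),
    "overlap")
})

test_that("subtype cutoffs are calibrated and classification is faithful", {
  sc <- small_cohort(seed = 31)
  cls <- lapply(sc$cohort$truth$classifier_genes, intersect, y = rownames(sc$z))
  scores <- subtype_scores(sc$z, cls)
  expect_equal(dim(scores), c(ncol(sc$z), 4))
  expect_error(subtype_cutoffs(sc$z, cls, q = 0.5), "q must lie")
  cuts <- subtype_cutoffs(sc$z, cls, seed = 31)
  calls <- classify_cells(scores, cuts)
  expect_true(all(calls$n_subtypes == lengths(calls$passing)))
  primary <- sc$cohort$truth$subtype_primary[names(calls$top)]
  expect_gte(mean(calls$top == primary, na.rm = TRUE), 0.9)
  # degenerate all-zero z: cutoff 0, nothing passes strictly
  z0 <- expression_matrix(matrix(0, 20, 6,
                                 dimnames = list(paste0("g", 1:20),
                                                 paste0("c", 1:6))),
                          "ZSCORE")
  cls0 <- list(PN = paste0("g", 1:3), N = paste0("g", 4:6),
               MES = paste0("g", 7:9), CL = paste0("g", 10:12))
  cuts0 <- subtype_cutoffs(z0, cls0, n_random = 10, seed = 1)
  expect_equal(unname(cuts0), rep(0, 4))
  calls0 <- classify_cells(subtype_scores(z0, cls0), cuts0)
  expect_true(all(calls0$n_subtypes == 0))
  expect_true(all(is.na(calls0$top)))
})

test_that("classification consistency counts matching top labels", {
  mk <- function(labels) {
    passing <- lapply(labels, function(l) if (is.na(l)) character(0) else l)
    names(passing) <- paste0("c", seq_along(labels))
    structure(list(passing = passing,
                   n_subtypes = setNames(lengths(passing), names(passing)),
                   top = setNames(labels, names(passing))),
              class = "SubtypeCall")
  }
  a <- mk(c("PN", "PN", "MES", NA, "CL", "N", "PN", "MES", "CL", "N"))
  expect_equal(classification_consistency(a, a), 100)
  b <- mk(c("PN", "PN", "MES", NA, "CL", "N", "PN", "CL", "MES", "PN"))
  expect_equal(classification_consistency(a, b), 70)
  perm <- mk(c("N", "N", "CL", "PN", "MES", "PN", "N", "CL", "MES", "CL"))
  expect_equal(classification_consistency(
    mk(rep(c("PN", "MES"), 5)), mk(rep(c("MES", "PN"), 5))), 0)
  short <- mk(c("PN", "PN"))
  expect_error(classification_consistency(a, short), "different cell sets")
})
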