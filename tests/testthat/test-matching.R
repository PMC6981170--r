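test_that("the pancreas catalog holds 11 distinct annotated patterns", {
  atlas <- pancreas_atlas_n4()
  map <- annotate_pancreas_atlas(atlas)
  ann <- setNames(pancreas_annotations()[names(map)], unname(map))
  catalog <- catalog_from_atlas(atlas, annotations = ann)
  expect_equal(nrow(catalog$patterns), 11)
  expect_false(anyDuplicated(apply(catalog$patterns, 1, paste,
                                   collapse = "")) > 0)
  # the all-off state is annotated as the marker-free state
  zero <- which(rowSums(catalog$patterns) == 0)
  expect_match(catalog$annotations[zero], "none of the major cell markers")
  # a state with values {0.98, 0.02, ...} binarizes to {1, 0, ...}
  fake <- atlas
  fake$states <- list(modifyList(atlas$states[[1]],
                                 list(x = setNames(c(0.98, 0.02, rep(0, 6)),
                                                   atlas$genes))))
  expect_equal(unname(catalog_from_atlas(fake)$patterns[1, ]),
               c(1L, 0L, rep(0L, 6)))
  # at the half-maximum threshold some saddles binarize onto attractor
  # patterns; both entries are kept and the collision is flagged
  expect_warning(catalog_from_atlas(atlas, include_transition = TRUE),
                 "collapse")
})

test_that("annotation covers every predicted pancreatic cell type", {
  map <- annotate_pancreas_atlas(pancreas_atlas_n4())
  expect_setequal(names(map),
                  c("TiP", "AciP", "AciP2", "TrP", "Ibeta", "Ialpha",
                    "acinar", "trunk", "ductal", "NKX61_only", "none",
                    "MP", "EEP", "LEP"))
  # saddle identities: MP/EEP/LEP are transition states
  expect_true(all(grepl("^T", map[c("MP", "EEP", "LEP")])))
  expect_true(all(grepl("^S", map[c("TiP", "TrP", "Ibeta")])))
})

test_that("pseudocount transforms follow the declared conventions", {
  m <- matrix(c(0, 9, 1, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_equal(transform_expression(m, "count")[1, 1], 1)   # count 0 -> 1
  expect_equal(transform_expression(m, "tpm")[2, 1], 10)    # TPM 9 -> 10
  expect_equal(transform_expression(m, "count", log2 = TRUE)[1, 1], 0)
  expect_error(transform_expression(m - 1), "negative")
  expect_match(attr(transform_expression(m, "tpm", log2 = TRUE),
                    "transform"), "tpm\\+1,log2")
})

test_that("zero-noise cells are assigned perfectly and zeros map to the null state", {
  catalog <- pancreas_catalog()
  spec <- generator_spec(catalog, cells_per_state = 5, on_mean = 50,
                         off_mean = 0, dispersion = Inf, dropout_prob = 0,
                         n_background_genes = 3, seed = 1)
  sim <- generate_cells(spec)
  asg <- assign_cells(sim$matrix, catalog)
  expect_identical(asg$assignment$label, sim$labels)
  # a cell with all core genes at 0 counts gets the all-zero state label
  zero_label <- catalog$labels[rowSums(catalog$patterns) == 0]
  zcell <- matrix(0, nrow = 8, ncol = 1,
                  dimnames = list(catalog$genes, "z"))
  expect_identical(assign_cells(zcell, catalog)$assignment$label, zero_label)
})

test_that("assignment is deterministic, order-invariant, and counts add up", {
  catalog <- pancreas_catalog()
  sim <- generate_cells(generator_spec(catalog, cells_per_state = 30,
                                       seed = 5))
  a1 <- assign_cells(sim$matrix, catalog, on_threshold = 5)
  a2 <- assign_cells(sim$matrix, catalog, on_threshold = 5)
  expect_identical(a1$assignment, a2$assignment)
  set.seed(9)
  perm <- sample(ncol(sim$matrix))
  a3 <- assign_cells(sim$matrix[, perm], catalog, on_threshold = 5)
  expect_identical(a3$assignment$label, a1$assignment$label[perm])
  expect_equal(unname(a3$summary), unname(a1$summary))
  expect_equal(sum(a1$summary), ncol(sim$matrix))
  # missing core gene errors by name
  expect_error(assign_cells(sim$matrix[-1, ], catalog), "PDX1")
  # gene_map resolves renamed rows
  m2 <- sim$matrix
  rownames(m2)[1] <- "Pdx1_ens"
  a4 <- assign_cells(m2, catalog, on_threshold = 5,
                     gene_map = c(PDX1 = "Pdx1_ens"))
  expect_identical(a4$assignment$label, a1$assignment$label)
})

test_that("endocrine-lineage progenitor states are all recovered from pattern-true cells", {
  atlas <- pancreas_atlas_n4()
  map <- annotate_pancreas_atlas(atlas)
  # marker-detection level 0.2 for saddle phenotypes keeps the progenitor
  # patterns (which express some markers at intermediate level) distinct
  catalog <- suppressWarnings(
    catalog_from_atlas(atlas, include_transition = TRUE,
                       transition_threshold = 0.2))
  endo <- c("MP", "TrP", "EEP", "LEP", "Ialpha", "Ibeta")
  # each endocrine state owns its pattern: it is the first catalog entry
  # carrying it, so exact matching resolves to that state
  keys <- apply(catalog$patterns, 1, paste, collapse = "")
  idx <- match(unname(map[endo]), catalog$labels)
  expect_identical(match(keys[idx], keys), idx)
  nps <- setNames(rep(20L, length(endo)), unname(map[endo]))
  sim <- generate_cells(generator_spec(catalog, cells_per_state = nps,
                                       dropout_prob = 0, dispersion = Inf,
                                       off_mean = 0, seed = 3))
  asg <- assign_cells(sim$matrix, catalog)
  expect_true(all(unname(map[endo]) %in% asg$assignment$label))
})

test_that("correlation clustering recovers block structure", {
  set.seed(21)
  # two duplicated cell blocks -> perfect recovery
  b1 <- matrix(rep(c(10, 0, 5, 0, 8), 6), nrow = 5)
  b2 <- matrix(rep(c(0, 7, 0, 9, 1), 6), nrow = 5)
  m <- cbind(b1, b2) + matrix(runif(60, 0, 0.01), 5)
  rownames(m) <- paste0("g", 1:5); colnames(m) <- paste0("c", 1:12)
  cl <- correlation_cluster(m, 2)
  expect_equal(length(unique(cl[1:6])), 1)
  expect_equal(length(unique(cl[7:12])), 1)
  expect_false(cl[1] == cl[7])
  expect_equal(unique(correlation_cluster(m, 1)), 1L)
  # constant cell triggers the zero-distance convention warning
  m2 <- cbind(m, const = rep(1, 5))
  expect_warning(correlation_cluster(m2, 2), "constant")
})

test_that("clustering a synthetic state mixture aligns with the true labels", {
  skip_if_not_installed("mclust")
  atlas <- pancreas_atlas_n4()
  catalog <- pancreas_catalog()
  pick <- rowSums(catalog$patterns) > 0 &
    !duplicated(apply(catalog$patterns, 1, paste, collapse = ""))
  idx <- which(pick)[1:4]
  sub <- catalog
  sub$patterns <- sub$patterns[idx, , drop = FALSE]
  sub$labels <- sub$labels[idx]
  sub$annotations <- sub$annotations[idx]
  # near-noiseless regime: alignment should be essentially perfect
  clean <- generate_cells(generator_spec(sub, 40, dropout_prob = 0,
                                         dispersion = 20, seed = 2))
  cl_clean <- correlation_cluster(log2(clean$matrix[1:8, ] + 1), 4)
  expect_gt(mclust::adjustedRandIndex(cl_clean, clean$labels), 0.9)
  # full generator noise (dispersion 2, dropout 0.1): alignment degrades
  # but stays far above chance
  noisy <- generate_cells(generator_spec(sub, 40, seed = 2))
  cl_noisy <- correlation_cluster(log2(noisy$matrix[1:8, ] + 1), 4)
  expect_gt(mclust::adjustedRandIndex(cl_noisy, noisy$labels), 0.4)
})

test_that("expression matrices round-trip through TSV and MatrixMarket", {
  catalog <- pancreas_catalog()
  sim <- generate_cells(generator_spec(catalog, cells_per_state = 3,
                                       n_background_genes = 2, seed = 8))
  tsv <- tempfile(fileext = ".tsv")
  write_expression_tsv(sim$matrix, tsv)
  back <- read_expression_tsv(tsv)
  expect_equal(back, sim$matrix + 0, ignore_attr = "dimnames")
  expect_identical(rownames(back), rownames(sim$matrix))

  mtx <- tempfile(fileext = ".mtx")
  gf <- tempfile(); bf <- tempfile()
  Matrix::writeMM(Matrix::Matrix(sim$matrix, sparse = TRUE), mtx)
  writeLines(rownames(sim$matrix), gf)
  writeLines(colnames(sim$matrix), bf)
  back2 <- read_expression_mtx(mtx, gf, bf)
  expect_equal(unname(back2), unname(sim$matrix + 0))
})
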