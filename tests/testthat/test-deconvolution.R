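test_that("reference profiles are normalized group means", {
  genes <- paste0("g", 1:5)
  counts <- rbind(c(10, 0, 5, 5, 0), c(2, 2, 2, 2, 2), c(4, 4, 4, 4, 4))
  colnames(counts) <- genes
  labels <- c("A", "B", "B")

  # raw mode: plain group means
  raw <- compute_reference_profiles(counts, labels, norm = "raw")
  expect_equal(unname(raw$mu["A", ]), c(10, 0, 5, 5, 0))
  expect_equal(unname(raw$mu["B", ]), c(3, 3, 3, 3, 3))

  # median mode: each cell scaled to the median total first
  med <- compute_reference_profiles(counts, labels)
  totals <- rowSums(counts)
  scaled <- counts * median(totals) / totals
  expect_equal(unname(med$mu["B", ]), unname(colMeans(scaled[2:3, ])))
  # two identical cells of one type average to either cell
  expect_equal(unname(med$mu["B", ]), unname(scaled[2, ]))

  expect_error(compute_reference_profiles(counts, c("A", "B", NA)), "NA")
})

test_that("reference profiles match a group-mean loop oracle on a 30-cell fixture", {
  withr::with_seed(17, {
    counts <- matrix(rpois(30 * 12, 20), 30, 12,
                     dimnames = list(NULL, paste0("g", 1:12)))
    labels <- sample(c("A", "B", "C"), 30, replace = TRUE)
  })
  prof <- compute_reference_profiles(counts, labels)
  scaled <- counts * median(rowSums(counts)) / rowSums(counts)
  for (t in c("A", "B", "C")) {
    oracle <- colMeans(scaled[labels == t, , drop = FALSE])
    expect_equal(unname(prof$mu[t, ]), unname(oracle), tolerance = 1e-12)
  }
})

test_that("split_spots evaluates the closed-form allocation", {
  # beta = (0.5, 0.5), mu_j = (2, 6): denominator 4, xhat = (2, 6)
  comp <- make_composition(list("1x1" = c("A", "B")))
  x <- Matrix::Matrix(matrix(8, 1, 1, dimnames = list("1x1", "g1")),
                      sparse = TRUE)
  mu <- matrix(c(2, 6), 2, 1, dimnames = list(c("A", "B"), "g1"))
  sub <- split_spots(x, comp, mu)
  expect_equal(unname(sub$rna[, "g1"]), c(2, 6))
  expect_equal(sub$meta$label, c("A", "B"))

  # one-hot composition: the single present type receives everything
  comp1 <- make_composition(list("1x1" = c("A", "A")), types = c("A", "B"))
  sub1 <- split_spots(x, comp1, mu)
  expect_equal(nrow(sub1$rna), 1)              # no sub-spot for beta = 0
  expect_equal(sub1$meta$label, "A")
  expect_equal(unname(sub1$rna[1, 1]), 8)

  # zero counts split to zeros
  x0 <- Matrix::Matrix(matrix(0, 1, 1, dimnames = list("1x1", "g1")),
                       sparse = TRUE)
  expect_true(all(split_spots(x0, comp, mu)$rna == 0))

  # a type in beta but not in mu is an error naming the type
  mu_bad <- matrix(1, 1, 1, dimnames = list("A", "g1"))
  expect_error(split_spots(x, comp, mu_bad), "B")
})

test_that("zero-denominator genes follow the fallback policy and are logged", {
  comp <- make_composition(list("1x1" = c("A", "B", "B", "B")))
  x <- Matrix::Matrix(matrix(4, 1, 1, dimnames = list("1x1", "g1")),
                      sparse = TRUE)
  mu0 <- matrix(0, 2, 1, dimnames = list(c("A", "B"), "g1"))
  sub <- split_spots(x, comp, mu0, fallback = "beta")
  expect_equal(unname(sub$rna[, "g1"]), c(1, 3))
  expect_equal(sub$log$event, "zero_denominator_beta")
  expect_equal(sub$log$item, "g1")

  dropped <- split_spots(x, comp, mu0, fallback = "drop")
  expect_true(all(dropped$rna == 0))
  expect_equal(dropped$log$event, "zero_denominator_drop")
})

test_that("splitting conserves counts and degenerates to proportional allocation", {
  ds <- small_dataset(seed = 19)
  comp <- compute_composition(ds$cells, types = ds$truth$cell_types)
  sub <- split_spots(ds$counts, comp, ds$truth$mu_true)
  cons <- check_conservation(sub, ds$counts)
  expect_true(cons$pass)
  expect_lte(cons$max_rel_err, 1e-9)

  # identical mu rows: xhat = x * beta exactly
  flat <- matrix(1, 3, ncol(ds$counts),
                 dimnames = list(ds$truth$cell_types, colnames(ds$counts)))
  sub_flat <- split_spots(ds$counts, comp, flat)
  B <- composition_matrix(comp)
  X <- as.matrix(ds$counts[rownames(B), ])
  for (r in sample(nrow(sub_flat$rna), 20)) {
    sid <- sub_flat$meta$spot_id[r]
    expect_equal(unname(sub_flat$rna[r, ]),
                 unname(X[sid, ] * B[sid, sub_flat$meta$label[r]]),
                 tolerance = 1e-12)
  }
})

test_that("splitting is equivariant under gene and type permutations", {
  ds <- small_dataset(seed = 23, n_cells = 400, n_genes = 30)
  types <- ds$truth$cell_types
  comp <- compute_composition(ds$cells, types = types)
  sub <- split_spots(ds$counts, comp, ds$truth$mu_true)

  gperm <- withr::with_seed(1, sample(colnames(ds$counts)))
  sub_g <- split_spots(ds$counts[, gperm], comp, ds$truth$mu_true)
  expect_equal(sub_g$rna[, colnames(sub$rna)], sub$rna)

  comp_p <- compute_composition(ds$cells, types = rev(types))
  sub_t <- split_spots(ds$counts, comp_p, ds$truth$mu_true[rev(types), ])
  expect_equal(sub_t$rna[rownames(sub$rna), ], sub$rna)
})

test_that("protein aggregation averages scaled vectors per spot and type", {
  cells <- tibble::tibble(
    cell_id = 1:5, x = c(0, 2, 4, 10, 20), y = c(0, 2, 0, 4, 5),
    area = 1, spot_id = c("1x1", "1x1", "1x1", "2x1", NA),
    label = c("A", "A", "B", "B", "A"),
    M = c(0.2, 0.6, 0.5, 0.9, 0.1))
  agg <- aggregate_protein_subspots(cells, markers = "M")
  a11 <- agg[agg$subspot_id == "1x1_A", ]
  expect_equal(a11$M, 0.4)
  expect_equal(a11$n_cells, 2L)
  expect_equal(c(a11$x, a11$y), c(1, 1))       # member-cell centroid
  expect_equal(agg[agg$subspot_id == "1x1_B", ]$M, 0.5)    # single cell
  expect_false("NA_A" %in% agg$subspot_id)      # dead-space cells ignored

  # group-mean oracle on a larger table
  big <- make_cells(200, markers = "M", seed = 31)
  big$spot_id <- sprintf("%dx1", sample(1:8, 200, replace = TRUE))
  big$label <- sample(c("A", "B"), 200, replace = TRUE)
  got <- aggregate_protein_subspots(big, markers = "M")
  for (r in seq_len(nrow(got))) {
    sel <- big$spot_id == got$spot_id[r] & big$label == got$label[r]
    expect_equal(got$M[r], mean(big$M[sel]), tolerance = 1e-12)
  }
})

test_that("paired sub-spot export matches rows, drops orphans, and round-trips", {
  ds <- small_dataset(seed = 29, n_cells = 600, n_genes = 25)
  comp <- compute_composition(ds$cells, types = ds$truth$cell_types)
  sub <- split_spots(ds$counts, comp, ds$truth$mu_true)
  scaled <- scale_features(ds$cells)
  prot <- aggregate_protein_subspots(scaled)
  dir <- withr::local_tempdir()
  rep <- withr::with_output_sink(nullfile(),
                                 export_wnn_inputs(sub, prot, dir))

  # every (spot, type) pair with beta > 0 has >= 1 cell here, so all match
  expect_equal(rep$n_written, nrow(sub$rna))
  expect_equal(rep$n_rna_only, 0)

  back <- read_gene_spot_matrix(dir, dialect = NULL)
  expect_equal(as.matrix(back), sub$rna[rownames(back), ])
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  protein <- readr::read_csv(file.path(dir, "protein.csv"),
                             show_col_types = FALSE)
  expect_identical(meta$subspot_id, rownames(back))
  expect_identical(protein$subspot_id, rownames(back))

  # an orphan protein row (no RNA partner) is dropped and counted
  prot2 <- dplyr::bind_rows(prot, dplyr::mutate(prot[1, ],
                                                subspot_id = "99x99_ghost"))
  rep2 <- export_wnn_inputs(sub, prot2, withr::local_tempdir())
  expect_equal(rep2$n_protein_only, 1)
})
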