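test_that("tissue masks are deterministic, connected, hole-free, and plausibly sized", {
  m1 <- simulate_tissue_mask(c(256, 256), 1, seed = 0)
  m2 <- simulate_tissue_mask(c(256, 256), 1, seed = 0)
  expect_identical(m1, m2)
  expect_equal(n_components(m1), 1)
  filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m1 * 1)))) > 0)
  expect_identical(unname(m1), unname(filled))          # no holes

  m3 <- simulate_tissue_mask(c(512, 512), 3, seed = 7)
  expect_gte(mean(m3), 0.2)
  expect_lte(mean(m3), 0.8)
  expect_equal(n_components(m3), 1)

  expect_error(simulate_tissue_mask(c(32, 256), 1), ">= 64")
  expect_error(simulate_tissue_mask(c(256, 256), 0), ">= 1")
})

test_that("generated cells respect the mask, the proportions, and the zero-noise limit", {
  truth <- tiny_truth()
  mask <- simulate_tissue_mask(c(256, 256), 2, seed = 1)
  cells <- simulate_cells(mask, 1000, truth, seed = 5)
  # every centroid is exactly on a foreground pixel centre
  expect_true(all(mask[cbind(cells$y + 1, cells$x + 1)]))
  # type counts within the binomial 99% interval around n * p = 500
  ci <- qbinom(c(0.005, 0.995), 1000, 0.5)
  nA <- sum(cells$label == truth$cell_types[1])
  expect_gte(nA, ci[1])
  expect_lte(nA, ci[2])
  # zero noise reproduces the protein means exactly
  exact <- simulate_cells(mask, 50, truth, noise_sdlog = 0, seed = 2)
  for (m in truth$markers) {
    expect_equal(exact[[m]], unname(truth$protein_means[exact$label, m]))
  }
  expect_error(simulate_cells(matrix(FALSE, 4, 4), 10, truth), "foreground")
})

test_that("spot counts follow the Poisson mixture with the stated depth", {
  truth <- tiny_truth(n_types = 2, n_genes = 25, seed = 3)
  # 400 identically composed spots give iid draws of the spot total
  cells <- tibble::tibble(
    spot_id = rep(sprintf("%dx%d", rep(1:20, each = 20), rep(1:20, 20)), each = 5),
    label = rep(rep(truth$cell_types, c(3, 2)), 400))
  x <- simulate_spot_counts(cells, truth, seed = 9)
  totals <- Matrix::rowSums(x)
  sem <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - truth$depth), 3 * sem)

  # a spot with no cells yields an all-zero row
  x2 <- simulate_spot_counts(cells, truth, spot_ids = c("1x1", "99x99"), seed = 9)
  expect_equal(sum(x2["99x99", ]), 0)

  # single-type spots: per-gene means match the known Poisson rates
  truth1 <- tiny_truth(n_types = 2, n_genes = 25, seed = 3)
  cells1 <- tibble::tibble(spot_id = cells$spot_id,
                           label = truth1$cell_types[1])
  x3 <- simulate_spot_counts(cells1, truth1, seed = 10)
  mu_norm <- truth1$mu_true / rowSums(truth1$mu_true)
  lambda <- truth1$depth * mu_norm[1, ]
  obs <- Matrix::colMeans(x3)
  sem_g <- sqrt(lambda / nrow(x3))
  expect_true(all(abs(obs - lambda) <= 3.5 * sem_g + 1e-9))
})

test_that("ground-truth composition and profiles reproduce expected counts (Monte Carlo)", {
  truth <- tiny_truth(n_types = 2, n_genes = 10, seed = 6)
  # one spot with 3 + 1 cells, replicated 10,000 times for iid draws
  n_rep <- 10000
  ids <- sprintf("%dx%d", rep(1:100, each = 100), rep(1:100, 100))
  cells <- tibble::tibble(spot_id = rep(ids, each = 4),
                          label = rep(rep(truth$cell_types, c(3, 1)), n_rep))
  x <- simulate_spot_counts(cells, truth, seed = 21)
  beta <- c(0.75, 0.25)
  mu_norm <- truth$mu_true / rowSums(truth$mu_true)
  expected <- truth$depth * as.numeric(beta %*% mu_norm)
  obs <- Matrix::colMeans(x)
  sem <- sqrt(expected / n_rep)
  expect_true(all(abs(obs - expected) <= 4 * sem))
})

test_that("transformed copies invert exactly and perturb intensities when asked", {
  cells <- make_cells(200, seed = 8)
  id <- similarity_transform()
  expect_equal(simulate_transformed_copy(cells, id, 0), cells)

  tf <- similarity_transform(10, 1, c(5, -3))
  moved <- simulate_transformed_copy(cells, tf, 0)
  back <- transform_points(moved, invert_transform(tf))
  expect_lt(max(abs(back$x - cells$x)), 1e-9)
  expect_lt(max(abs(back$y - cells$y)), 1e-9)
  expect_equal(moved$DAPI, cells$DAPI)    # no intensity noise

  noisy <- simulate_transformed_copy(cells, id, intensity_noise_sd = 5, seed = 2)
  expect_false(identical(noisy$DAPI, cells$DAPI))
  expect_true(all(noisy$DAPI >= 0))
})

test_that("every generator is deterministic under a fixed seed", {
  truth <- tiny_truth()
  mask <- simulate_tissue_mask(c(128, 128), 2, seed = 4)
  expect_identical(simulate_cells(mask, 100, truth, seed = 3),
                   simulate_cells(mask, 100, truth, seed = 3))
  cells <- tibble::tibble(spot_id = rep("1x1", 6),
                          label = rep(truth$cell_types, 3))
  a <- simulate_spot_counts(cells, truth, seed = 5)
  b <- simulate_spot_counts(cells, truth, seed = 5)
  expect_equal(as.matrix(a), as.matrix(b))
  ds1 <- small_dataset(seed = 13, n_cells = 300, n_genes = 30)
  ds2 <- small_dataset(seed = 13, n_cells = 300, n_genes = 30)
  expect_equal(ds1$cells, ds2$cells)
  expect_equal(as.matrix(ds1$counts), as.matrix(ds2$counts))
})
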