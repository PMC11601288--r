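test_that("feature extraction sums channel signal per cell", {
  lab <- matrix(0L, 4, 5)
  lab[2, 2] <- 1L; lab[2, 3] <- 1L      # a 2-pixel cell
  lab[4, 5] <- 2L                        # a 1-pixel cell
  ch <- matrix(0, 4, 5)
  ch[2, 2] <- 3; ch[2, 3] <- 4; ch[4, 5] <- 10
  cells <- extract_cell_features(lab, list(ch), "M")
  expect_equal(cells$M[cells$cell_id == 1], 7)
  expect_equal(cells$area[cells$cell_id == 1], 2)
  # centroid of pixels (r=2, c=2) and (r=2, c=3): x = mean(1, 2), y = 1
  expect_equal(cells$x[cells$cell_id == 1], 1.5)
  expect_equal(cells$y[cells$cell_id == 1], 1)

  zero <- extract_cell_features(lab, list(matrix(0, 4, 5)), "Z")
  expect_true(all(zero$Z == 0))

  expect_error(extract_cell_features(lab, list(matrix(0, 3, 5)), "M"),
               "mismatch")
  expect_error(extract_cell_features(matrix(0L, 4, 5), list(ch), "M"),
               "no positive labels")
})

test_that("extraction matches a per-pixel brute-force loop on a 50-cell image", {
  truth <- tiny_truth()
  mask <- simulate_tissue_mask(c(96, 96), 1, seed = 2)
  cells <- simulate_cells(mask, 50, truth, seed = 3)
  img <- simulate_cell_image(cells, c(110, 110))
  got <- extract_cell_features(img$label_mask, img$channels, img$markers)

  for (m in img$markers) {
    oracle <- sapply(got$cell_id, function(id) {
      s <- 0
      for (r in seq_len(nrow(img$label_mask))) {
        for (cc in seq_len(ncol(img$label_mask))) {
          if (img$label_mask[r, cc] == id) s <- s + img$channels[r, cc, m]
        }
      }
      s
    })
    expect_equal(got[[m]], unname(oracle), tolerance = 1e-12)
  }
  # rendering guarantees the per-cell sums equal the tabulated intensities
  rendered <- got$cell_id
  expect_equal(got$DAPI, unname(cells$DAPI[match(rendered, cells$cell_id)]),
               tolerance = 1e-9)
})

test_that("the size/nuclear filter matches a brute-force oracle and keeps ties", {
  cells <- make_cells(1000, seed = 4)
  kept <- filter_cells(cells)
  qa <- quantile(cells$area, c(0.05, 0.95), names = FALSE)
  qd <- quantile(cells$DAPI, 0.1, names = FALSE)
  oracle <- cells[cells$area >= qa[1] & cells$area <= qa[2] &
                    cells$DAPI > qd, ]
  expect_equal(kept, oracle)
  expect_lte(nrow(kept), nrow(cells))

  # all-identical nuclear signal: strict > would drop everything; flagged
  tied <- cells
  tied$DAPI <- 5
  tied$area <- 100
  expect_warning(out <- filter_cells(tied), "skipped")
  expect_equal(nrow(out), nrow(tied))

  expect_error(filter_cells(cells, dapi_marker = "nope"), "not found")
})

test_that("quantile scaling maps the anchors to 0/1 with interpolated quantiles", {
  cells <- tibble::tibble(cell_id = 1:100, x = 0, y = 0, area = 1,
                          M = as.numeric(1:100))
  scaled <- scale_features(cells, area_normalize = FALSE)
  anchors <- attr(scaled, "anchors")
  # type-7 interpolated quantiles of 1..100
  expect_equal(anchors$lo, 5.95)
  expect_equal(anchors$hi, 95.05)
  oracle <- pmin(1, pmax(0, (cells$M - 5.95) / (95.05 - 5.95)))
  expect_equal(scaled$M, oracle)
  # the value mapping: 5.95 -> 0, 95.05 -> 1, 50.5 -> 0.5
  expect_equal((50.5 - anchors$lo) / (anchors$hi - anchors$lo), 0.5)
  expect_equal(min(scaled$M), 0)
  expect_equal(max(scaled$M), 1)
})

test_that("area normalization divides before scaling and degenerate markers are flagged", {
  cells <- tibble::tibble(cell_id = 1:50, x = 0, y = 0,
                          area = rep(c(1, 2), 25),
                          M = as.numeric(1:50), K = 7 * rep(c(1, 2), 25))
  expect_warning(scaled <- scale_features(cells), "Constant marker")
  expect_true(all(scaled$K == 0))
  # oracle on the area-normalized values
  v <- cells$M / cells$area
  qs <- quantile(v, c(0.05, 0.95), names = FALSE)
  expect_equal(scaled$M, pmin(1, pmax(0, (v - qs[1]) / (qs[2] - qs[1]))))
})

test_that("re-scaling already scaled data with 0/1 anchors is the identity", {
  withr::with_seed(10, {
    v <- c(rep(0, 10), runif(80), rep(1, 10))
  })
  cells <- tibble::tibble(cell_id = seq_along(v), x = 0, y = 0, area = 1, M = v)
  scaled <- scale_features(cells, area_normalize = FALSE)
  expect_equal(attr(scaled, "anchors")$lo, 0)
  expect_equal(attr(scaled, "anchors")$hi, 1)
  expect_equal(scaled$M, v)
  # output never escapes [0, 1]
  rnd <- make_cells(300, seed = 6)
  s2 <- scale_features(rnd)
  for (m in marker_names(s2)) {
    expect_true(all(s2[[m]] >= 0 & s2[[m]] <= 1))
  }
})
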