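test_that("spatial binning floors coordinates and averages members", {
  cells <- tibble::tibble(cell_id = 1:3,
                          x = c(250, 20, 30), y = c(150, 10, 15),
                          area = 1, M = c(5, 2, 4))
  b <- bin_features(cells, markers = "M", bin_size = 100)
  one <- b[b$bin_row == 1 & b$bin_col == 2, ]
  expect_equal(one$M, 5)
  expect_equal(one$n, 1L)
  both <- b[b$bin_row == 0 & b$bin_col == 0, ]
  expect_equal(both$M, 3)                        # mean of 2 and 4
  expect_equal(both$n, 2L)
  expect_equal(nrow(b), 2)                       # empty bins absent

  # negative coordinates floor consistently
  neg <- tibble::tibble(cell_id = 1, x = -10, y = -150, area = 1, M = 1)
  bn <- bin_features(neg, "M", 100)
  expect_equal(c(bn$bin_row, bn$bin_col), c(-2, -1))

  expect_error(bin_features(cells[0, ], "M"), "empty")
  expect_error(bin_features(cells, "M", bin_size = 0), "positive")
})

test_that("binning matches a brute-force double loop on a 500-cell fixture", {
  cells <- make_cells(500, markers = c("DAPI", "CD3"), seed = 21)
  got <- bin_features(cells, bin_size = 100)
  rows <- floor(cells$y / 100); cols <- floor(cells$x / 100)
  for (r in seq_len(nrow(got))) {
    sel <- rows == got$bin_row[r] & cols == got$bin_col[r]
    expect_equal(got$n[r], sum(sel))
    expect_equal(got$DAPI[r], mean(cells$DAPI[sel]), tolerance = 1e-12)
    expect_equal(got$CD3[r], mean(cells$CD3[sel]), tolerance = 1e-12)
  }
  expect_equal(sum(got$n), 500L)
})

test_that("binned correlation is 1 for self, -1 for negated, and symmetric", {
  cells <- make_cells(400, markers = c("DAPI", "CD3"), seed = 5)
  b <- bin_features(cells, bin_size = 50)
  self <- correlate_bins(b, b)
  expect_equal(self$r, rep(1, 2), tolerance = 1e-12)

  flipped <- cells
  flipped$CD3 <- -flipped$CD3
  b2 <- bin_features(flipped, bin_size = 50)
  res <- correlate_bins(b, b2)
  expect_equal(res$r[res$marker == "CD3"], -1, tolerance = 1e-12)

  ab <- correlate_bins(b, b2)
  ba <- correlate_bins(b2, b)
  expect_equal(ab$r, ba$r)

  # zero-variance marker flagged as undefined
  const <- cells
  const$DAPI <- 3
  bc <- bin_features(const, bin_size = 50)
  expect_warning(rc <- correlate_bins(b, bc), "Zero-variance")
  expect_true(is.na(rc$r[rc$marker == "DAPI"]))
})

test_that("correlation decreases monotonically with intensity noise after exact realignment", {
  truth <- tiny_truth()
  mask <- simulate_tissue_mask(c(400, 400), 2, seed = 9)
  cells <- simulate_cells(mask, 1500, truth, seed = 10)
  scaled <- scale_features(cells)
  tf <- similarity_transform(10, 1, c(30, -12))
  lm_a <- tibble::tibble(x = c(10, 350, 40, 300, 120, 220),
                         y = c(20, 40, 330, 310, 180, 90))
  lm_b <- transform_points(lm_a, tf)
  rs <- sapply(c(0, 0.1, 0.3), function(sd) {
    copy <- simulate_transformed_copy(scaled, tf, intensity_noise_sd = sd,
                                      seed = 33)
    aligned <- transform_points(copy, fit_landmark_affine(lm_b, lm_a))
    res <- correlate_bins(bin_features(scaled, bin_size = 100),
                          bin_features(aligned, bin_size = 100))
    mean(res$r)
  })
  # noiseless duplicate: near-perfect (cells restored to ~1e-12 px, so the
  # rare cell sitting exactly on a bin boundary may still switch bins)
  expect_gt(rs[1], 0.99)
  expect_lt(rs[2], rs[1])
  expect_lt(rs[3], rs[2])
})

test_that("extreme bin sizes behave gracefully", {
  cells <- make_cells(100, markers = "DAPI", seed = 2)
  big <- bin_features(cells, "DAPI", bin_size = 1e9)   # everything in 1 bin
  expect_equal(nrow(big), 1)
  expect_error(correlate_bins(big, big), "at least 3")
  tiny <- bin_features(cells, "DAPI", bin_size = 1e-3) # per-cell bins
  expect_equal(nrow(tiny), 100)
  expect_equal(correlate_bins(tiny, tiny)$r, 1)
})
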