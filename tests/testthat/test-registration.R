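test_that("boundary detection thresholds and fills holes", {
  # bright disk on dark background
  disk <- disk_mask(c(128, 128), c(64, 64), 30)
  img <- disk * 1 + 0.02
  mask <- detect_tissue_boundary(img, sigma_px = 2)
  inter <- sum(mask & disk); uni <- sum(mask | disk)
  expect_gte(inter / uni, 0.95)
  filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(mask * 1)))) > 0)
  expect_identical(which(mask), which(filled))    # hole-free

  # bright annulus comes back as the filled disk
  outer <- disk_mask(c(128, 128), c(64, 64), 30)
  inner <- disk_mask(c(128, 128), c(64, 64), 15)
  ann <- (outer & !inner) * 1
  m2 <- detect_tissue_boundary(ann, sigma_px = 1)
  expect_true(m2[65, 65])                       # centre hole is filled
  inter2 <- sum(m2 & outer); uni2 <- sum(m2 | outer)
  expect_gte(inter2 / uni2, 0.9)

  expect_error(detect_tissue_boundary(matrix(1, 64, 64)), "constant")
})

test_that("boundary detection recovers a noisy synthetic blob (Jaccard >= 0.95)", {
  blob <- simulate_tissue_mask(c(256, 256), 2, seed = 12)
  withr::with_seed(1, {
    img <- blob * 1 + matrix(rnorm(length(blob), 0, 0.15), nrow(blob))
  })
  mask <- detect_tissue_boundary(img, sigma_px = 5)
  jac <- sum(mask & blob) / sum(mask | blob)
  expect_gte(jac, 0.95)
})

test_that("boundary detection is approximately scale-equivariant", {
  blob <- simulate_tissue_mask(c(128, 128), 1, seed = 3)
  img <- blob * 1 + 0.05
  m1 <- detect_tissue_boundary(img, sigma_px = 2)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(t(img)), 256, 256))
  m2 <- detect_tissue_boundary(t(up), sigma_px = 4)
  # block-average the upsampled mask back down and compare
  down <- spotsplitr:::.block_reduce(matrix(as.numeric(m2), 256), 2) >= 0.5
  jac <- sum(down & m1) / sum(down | m1)
  expect_gte(jac, 0.95)
})

test_that("spot rasterization renders squares at the declared resolution", {
  layout <- channel_layout(n_a = 1, n_b = 1, channel_width = 25, pitch = 50)
  spots <- build_spot_grid(layout)
  spots$tissue <- TRUE
  r1 <- rasterize_spot_mask(spots, px_per_pitch = 10)
  expect_equal(n_components(r1), 1)
  expect_equal(sum(r1), 25)                     # 5 x 5 px square at 5 um/px

  # full occupancy: foreground fraction = (width / pitch)^2
  layout2 <- channel_layout(n_a = 8, n_b = 8, channel_width = 25, pitch = 50)
  spots2 <- build_spot_grid(layout2)
  spots2$tissue <- TRUE
  r2 <- rasterize_spot_mask(spots2, px_per_pitch = 10)
  expect_equal(mean(r2), (25 / 50)^2)

  # checkerboard occupancy: one component per occupied spot
  spots3 <- build_spot_grid(layout2)
  spots3$tissue <- (spots3$ai + spots3$bi) %% 2 == 0
  r3 <- rasterize_spot_mask(spots3, px_per_pitch = 10)
  expect_equal(n_components(r3), sum(spots3$tissue))

  expect_error(rasterize_spot_mask(dplyr::mutate(spots, tissue = FALSE)),
               "No tissue")
})

test_that("similarity fitting recovers identity, translation, and a general warp", {
  m <- simulate_tissue_mask(c(192, 192), 2, seed = 3)

  fid <- fit_similarity(m, m)
  expect_lte(abs(fid$rotation_deg), 0.5)
  expect_lte(abs(fid$scale - 1), 0.01)
  expect_lte(max(abs(fid$translation)), 1)

  tt <- similarity_transform(0, 1, c(40, 7))
  ft <- fit_similarity(m, warp_image(m, tt, output_dim = c(256, 256)))
  expect_lte(max(abs(ft$translation - c(40, 7))), 1)

  tw <- similarity_transform(10, 1.2, c(30, -15))
  fixed <- warp_image(m, tw, output_dim = c(256, 256))
  fw <- fit_similarity(m, fixed)
  expect_lte(abs(fw$rotation_deg - 10), 1)
  expect_lte(abs(fw$scale / 1.2 - 1), 0.02)
  expect_lte(max(abs(fw$translation - c(30, -15))), 2)
  # the optimizer never does worse than the generating transform
  expect_lte(attr(fw, "loss"), similarity_loss(m, fixed, tw) + 1e-6)

  expect_error(fit_similarity(matrix(FALSE, 10, 10), m), "empty")
})

test_that("landmark affine fits reproduce known transforms and least-squares residuals", {
  pts <- tibble::tibble(x = c(0, 10, 3, 8, 1, 6), y = c(0, 2, 9, 7, 5, 1))
  fit0 <- fit_landmark_affine(pts, pts)
  expect_lt(max(abs(fit0$m - cbind(diag(2), c(0, 0)))), 1e-9)
  expect_equal(attr(fit0, "rss"), 0, tolerance = 1e-18)

  A <- matrix(c(1.1, -0.2, 0.15, 0.95, 12, -4), 2, 3)
  target <- transform_points(pts, affine_transform(A))
  fit1 <- fit_landmark_affine(pts, target)
  expect_lt(max(abs(fit1$m - A)), 1e-6)

  # noisy pairs: residuals equal the normal-equations (lm) solution
  withr::with_seed(5, {
    noisy <- target
    noisy$x <- noisy$x + rnorm(6, 0, 0.5)
    noisy$y <- noisy$y + rnorm(6, 0, 0.5)
  })
  fit2 <- fit_landmark_affine(pts, noisy)
  lmfit <- lm(cbind(noisy$x, noisy$y) ~ pts$x + pts$y)
  expect_equal(attr(fit2, "rss"), sum(residuals(lmfit)^2), tolerance = 1e-8)
  oracle_m <- rbind(c(coef(lmfit)[2:3, 1], coef(lmfit)[1, 1]),
                    c(coef(lmfit)[2:3, 2], coef(lmfit)[1, 2]))
  expect_lt(max(abs(fit2$m - oracle_m)), 1e-8)

  expect_error(fit_landmark_affine(pts[1:2, ], pts[1:2, ]), "At least 3")
  coll <- tibble::tibble(x = 1:4, y = 2 * (1:4))
  expect_error(fit_landmark_affine(coll, coll), "collinear")
})

test_that("solidifying a spot raster bridges inter-channel gaps", {
  layout <- channel_layout(n_a = 6, n_b = 6, channel_width = 25, pitch = 50)
  spots <- build_spot_grid(layout)
  spots$tissue <- TRUE
  r <- rasterize_spot_mask(spots, px_per_pitch = 10)
  expect_equal(n_components(r), 36)
  solid <- solidify_spot_mask(r)
  expect_equal(n_components(solid), 1)
  expect_true(all(solid[r]))
})
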