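#' Detect the tissue boundary in an intensity image
#'
#' Smooths the image with a Gaussian filter, thresholds the smoothed image
#' with Otsu's method (256-bin histogram), and fills holes, yielding a
#' hole-free binary tissue mask suitable for mask-based registration.
#'
#' @param image 2D numeric matrix (rows = y, columns = x).
#' @param sigma_px Gaussian smoothing sigma in pixels. Default 5.
#' @return Logical matrix of the same dimensions; attribute `threshold`
#'   carries the Otsu cut on the smoothed image.
#' @export
detect_tissue_boundary <- function(image, sigma_px = 5) {
  image <- as.matrix(image)
  if (!is.numeric(image) || length(dim(image)) != 2) {
    abort("`image` must be a 2D numeric matrix.")
  }
  rng <- range(image, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    abort("`image` is constant; Otsu thresholding is undefined.")
  }
  # EBImage works column-major with x as the first index; transpose in/out so
  # our row = y convention is preserved.
  img <- EBImage::Image(t(image))
  if (sigma_px > 0) img <- EBImage::gblur(img, sigma = sigma_px)
  v <- EBImage::imageData(img)
  v <- (v - min(v)) / (max(v) - min(v))
  thr <- EBImage::otsu(EBImage::Image(v), range = c(0, 1), levels = 256)
  fg <- EBImage::fillHull(EBImage::Image(v > thr))
  mask <- t(EBImage::imageData(fg) > 0)
  if (!any(mask)) abort("Boundary detection produced an empty mask.")
  attr(mask, "threshold") <- as.numeric(thr)
  mask
}

#' Rasterize tissue-covered spots into a binary mask
#'
#' Renders the union of the squares of tissue-flagged spots as the
#' low-resolution fixed image that the imaging-side tissue mask is registered
#' against. The raster's pixel grid is tied back to the micrometre spot frame
#' through the `um_per_px` and `origin_um` attributes.
#'
#' @param spots A spot table from [build_spot_grid()], with a `tissue` column
#'   or an explicit `tissue_flags` vector.
#' @param tissue_flags Optional logical vector overriding `spots$tissue`.
#' @param px_per_pitch Raster resolution: pixels per spot pitch. Default 10.
#' @return Logical matrix with attributes `um_per_px` (micrometres per raster
#'   pixel) and `origin_um` (xy of the centre of pixel (0, 0)).
#' @export
rasterize_spot_mask <- function(spots, tissue_flags = NULL, px_per_pitch = 10) {
  layout <- attr(spots, "layout")
  if (is.null(layout)) abort("`spots` must carry a `layout` attribute (see build_spot_grid()).")
  flags <- tissue_flags %||% spots$tissue
  if (is.null(flags)) abort("No tissue flags: supply `tissue_flags` or a `tissue` column.")
  keep <- spots[as.logical(flags), , drop = FALSE]
  if (nrow(keep) == 0) abort("No tissue-covered spots to rasterize.")

  um_per_px <- layout$pitch / px_per_pitch
  half <- layout$channel_width / 2
  # raster covers the full grid bounding box plus half a pitch margin
  x0 <- layout$origin[1] - layout$pitch / 2
  y0 <- layout$origin[2] - layout$pitch / 2
  nx <- ceiling(layout$n_a * layout$pitch / um_per_px)
  ny <- ceiling(layout$n_b * layout$pitch / um_per_px)
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  # pixel (r, c) centre in um: (x0 + (c-0.5)*um_per_px, y0 + (r-0.5)*um_per_px)
  px_x <- x0 + (seq_len(nx) - 0.5) * um_per_px
  px_y <- y0 + (seq_len(ny) - 0.5) * um_per_px
  for (i in seq_len(nrow(keep))) {
    cs <- which(px_x >= keep$x[i] - half & px_x < keep$x[i] + half)
    rs <- which(px_y >= keep$y[i] - half & px_y < keep$y[i] + half)
    mask[rs, cs] <- TRUE
  }
  attr(mask, "um_per_px") <- um_per_px
  # centre of pixel (0,0) in 0-based pixel coords corresponds to (r,c)=(1,1)
  attr(mask, "origin_um") <- c(x0 + 0.5 * um_per_px, y0 + 0.5 * um_per_px)
  attr(mask, "px_per_pitch") <- px_per_pitch
  mask
}

#' Close a rasterized spot mask into a solid tissue silhouette
#'
#' The spot raster is a lattice of disjoint squares separated by dead-space
#' gaps; for mask-based registration against a solid imaging-side tissue
#' mask, the gaps are bridged by a morphological closing (box kernel wider
#' than the inter-spot gap) followed by hole filling.
#'
#' @param mask A raster from [rasterize_spot_mask()].
#' @param kernel_px Closing kernel width (px); default `px_per_pitch + 1`
#'   inferred from the raster metadata, enough to bridge one gap.
#' @return Logical matrix with the raster's metadata attributes preserved.
#' @export
solidify_spot_mask <- function(mask, kernel_px = NULL) {
  if (is.null(kernel_px)) {
    ppp <- attr(mask, "px_per_pitch")
    kernel_px <- if (is.null(ppp)) 11L else as.integer(ppp) + 1L
  }
  kernel_px <- max(3L, as.integer(kernel_px))
  if (kernel_px %% 2 == 0) kernel_px <- kernel_px + 1L
  br <- EBImage::makeBrush(kernel_px, shape = "box")
  img <- EBImage::Image(t(matrix(as.numeric(mask), nrow(mask))))
  out <- EBImage::fillHull(EBImage::closing(img, br))
  res <- t(EBImage::imageData(out) > 0)
  attr(res, "um_per_px") <- attr(mask, "um_per_px")
  attr(res, "origin_um") <- attr(mask, "origin_um")
  res
}

#' Convert raster pixel coordinates to micrometre spot-frame coordinates
#'
#' @param points Data frame with `x`, `y` in 0-based pixel coordinates of a
#'   raster produced by [rasterize_spot_mask()].
#' @param raster The raster mask (for its `um_per_px` / `origin_um` metadata).
#' @return `points` with `x`, `y` replaced by micrometre coordinates.
#' @export
raster_px_to_um <- function(points, raster) {
  u <- attr(raster, "um_per_px")
  o <- attr(raster, "origin_um")
  if (is.null(u) || is.null(o)) abort("`raster` lacks um_per_px/origin_um metadata.")
  points$x <- o[1] + points$x * u
  points$y <- o[2] + points$y * u
  points
}

# zero-pad an image by two pixels on every side (for clamped sampling)
.pad_zero <- function(img) {
  p <- matrix(0, nrow(img) + 4, ncol(img) + 4)
  p[3:(nrow(img) + 2), 3:(ncol(img) + 2)] <- img
  p
}

# bilinear sampling of a zero-padded image at 0-based (x, y) of the original;
# everything outside the original support reads the zero border (clamped
# samples land on an all-zero border pair, so they interpolate to 0)
.sample_bilinear_padded <- function(pad, x, y) {
  nrp <- nrow(pad)
  nr <- nrp - 4; nc <- ncol(pad) - 4
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  xi <- pmin.int(pmax.int(x0, -2), nc) + 3
  yi <- pmin.int(pmax.int(y0, -2), nr) + 3
  i00 <- (xi - 1) * nrp + yi
  v00 <- pad[i00]
  v01 <- pad[i00 + nrp]
  v10 <- pad[i00 + 1]
  v11 <- pad[i00 + nrp + 1]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

# bilinear sampling of `img` at 0-based (x, y); 0 outside the support
.sample_bilinear <- function(img, x, y) {
  .sample_bilinear_padded(.pad_zero(img), x, y)
}

#' Warp an image or mask through a transform
#'
#' Inverse-mapping resampler: each output pixel samples the input at the
#' transform's preimage with bilinear interpolation. Logical inputs are
#' resampled as 0/1 and thresholded at 0.5.
#'
#' @param image 2D numeric or logical matrix in the moving frame.
#' @param transform Transform mapping moving-frame points to fixed-frame
#'   points (0-based pixel coordinates, x = column).
#' @param output_dim Integer `(rows, cols)` of the output; defaults to
#'   `dim(image)`.
#' @return Matrix of dimension `output_dim`, logical when `image` is logical.
#' @export
warp_image <- function(image, transform, output_dim = dim(image)) {
  was_logical <- is.logical(image)
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  inv <- invert_transform(transform)
  nr <- output_dim[1]; nc <- output_dim[2]
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  src <- transform_points(cbind(gx, gy), inv)
  vals <- .sample_bilinear(img, src[, 1], src[, 2])
  out <- matrix(vals, nr, nc)
  if (was_logical) out <- out >= 0.5
  out
}

# float render of a mask for a piecewise-smooth registration loss
.soft_mask <- function(mask, sigma = 1.5) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sigma > 0) m <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma)))
  m
}

.mask_moments <- function(m) {
  w <- which(m > 0, arr.ind = TRUE)
  v <- m[m > 0]
  x <- w[, 2] - 1; y <- w[, 1] - 1
  tot <- sum(v)
  cx <- sum(v * x) / tot; cy <- sum(v * y) / tot
  r2 <- sum(v * ((x - cx)^2 + (y - cy)^2)) / tot
  list(centroid = c(cx, cy), mass = tot, rgyr = sqrt(r2))
}

# block-mean downsampling by an integer factor (pads the margins with 0)
.block_reduce <- function(m, f) {
  if (f <= 1) return(m)
  nr <- ceiling(nrow(m) / f) * f
  nc <- ceiling(ncol(m) / f) * f
  p <- matrix(0, nr, nc)
  p[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  a <- array(p, dim = c(f, nr / f, nc))
  s <- colSums(a)                       # (nr/f) x nc
  a2 <- array(t(s), dim = c(f, nc / f, nr / f))
  t(colSums(a2)) / f^2
}

#' Fit a similarity transform between two binary masks
#'
#' Finds the rotation + uniform scale + translation minimizing the mean
#' squared difference between the warped moving mask and the fixed mask.
#' Masks are float-rendered (lightly Gaussian-smoothed) so the loss is
#' piecewise smooth; the search is a closed-form initialization from mask
#' centroids and second moments, a coarse grid over rotation and scale about
#' it, and Nelder-Mead refinement.
#'
#' @param moving,fixed Logical (or 0/1 numeric) masks. The imaging-side mask
#'   is the moving image; the rasterized spot mask is the fixed image.
#' @param rotation_grid_deg Coarse grid of candidate rotations, degrees.
#' @param scale_grid Multiplicative factors applied to the moment-based scale
#'   initialization.
#' @param allow_reflection Also try a reflected similarity and keep the lower
#'   loss. Default `FALSE`: adjacent sections are not mirrored.
#' @param render_sigma Sigma (px) of the float rendering.
#' @return A `similarity_transform` with attributes `loss` (mean squared
#'   difference at the optimum) and `n_px` (fixed-frame pixel count); `tidy()`
#'   and `glance()` methods apply.
#' @export
fit_similarity <- function(moving, fixed,
                           rotation_grid_deg = seq(-180, 171, by = 9),
                           scale_grid = c(0.9, 1, 1.1),
                           allow_reflection = FALSE,
                           render_sigma = 1.5) {
  if (!any(moving)) abort("`moving` mask is empty.")
  if (!any(fixed)) abort("`fixed` mask is empty.")
  mov_num <- matrix(as.numeric(moving), nrow(moving))
  fix_num <- matrix(as.numeric(fixed), nrow(fixed))

  # parametrization about the moving centroid: p' = s R F (p - cm) + cf + u;
  # inverse map: p = F' R' ((p' - cf - u) / s) + cm
  make_loss <- function(mv, fx) {
    mm <- .mask_moments(mv)
    mf <- .mask_moments(fx)
    mvp <- .pad_zero(mv)
    nr <- nrow(fx); nc <- ncol(fx)
    gx <- rep(seq_len(nc) - 1, each = nr)
    gy <- rep(seq_len(nr) - 1, times = nc)
    fxv <- as.numeric(fx)
    loss <- function(par, reflect) {
      th <- par[1] * pi / 180; s <- exp(par[2]); u <- par[3:4]
      ct <- cos(th); st <- sin(th)
      dx <- (gx - mf$centroid[1] - u[1]) / s
      dy <- (gy - mf$centroid[2] - u[2]) / s
      sx <- ct * dx + st * dy
      sy <- -st * dx + ct * dy
      if (reflect) sx <- -sx
      vals <- .sample_bilinear_padded(mvp, sx + mm$centroid[1],
                                      sy + mm$centroid[2])
      mean((vals - fxv)^2)
    }
    list(loss = loss, mm = mm, mf = mf, s0 = mf$rgyr / mm$rgyr)
  }

  full <- make_loss(.soft_mask(mov_num, render_sigma),
                    .soft_mask(fix_num, render_sigma))
  # coarse level for the grid search: block-downsample to ~96 px
  f <- max(1L, floor(min(dim(fix_num), dim(mov_num)) / 96))
  coarse <- if (f > 1) {
    make_loss(.soft_mask(.block_reduce(mov_num, f), render_sigma),
              .soft_mask(.block_reduce(fix_num, f), render_sigma))
  } else full

  run_side <- function(reflect) {
    cand <- expand.grid(th = rotation_grid_deg, sf = scale_grid)
    losses <- vapply(seq_len(nrow(cand)), function(i) {
      coarse$loss(c(cand$th[i], log(coarse$s0 * cand$sf[i]), 0, 0), reflect)
    }, numeric(1))
    ord <- order(losses)[seq_len(min(2, nrow(cand)))]
    best_c <- NULL
    for (i in ord) {
      st <- c(cand$th[i], log(coarse$s0 * cand$sf[i]), 0, 0)
      fit <- optim(st, coarse$loss, reflect = reflect, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10))
      if (is.null(best_c) || fit$value < best_c$value) best_c <- fit
    }
    # promote the coarse optimum to full resolution and polish
    start <- best_c$par
    if (f > 1) start[3:4] <- start[3:4] * f
    fit <- optim(start, full$loss, reflect = reflect, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-11))
    fit <- optim(fit$par, full$loss, reflect = reflect, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-12))
    fit$reflect <- reflect
    fit
  }

  best <- run_side(FALSE)
  if (allow_reflection) {
    alt <- run_side(TRUE)
    if (alt$value < best$value) best <- alt
  }

  mm <- full$mm; mf <- full$mf
  th <- best$par[1]; s <- exp(best$par[2]); u <- best$par[3:4]
  th <- ((th + 180) %% 360) - 180
  # convert centroid-anchored parameters to canonical t = cf + u - s R F cm
  tmp <- similarity_transform(th, s, c(0, 0), reflect = best$reflect)
  A <- transform_matrix(tmp)[, 1:2]
  tr <- mf$centroid + u - as.numeric(A %*% mm$centroid)
  out <- similarity_transform(th, s, tr, reflect = best$reflect)
  if (!is.finite(best$value)) abort("Similarity fit failed: non-finite loss at optimum.")
  # diagnose empty overlap at the optimum
  chk <- warp_image(matrix(as.numeric(moving), nrow(moving)), out, dim(fixed))
  if (sum(chk >= 0.5 & fixed) == 0) {
    abort("Similarity fit converged to a transform with no mask overlap; check inputs or widen the search grids.")
  }
  attr(out, "loss") <- best$value
  attr(out, "n_px") <- length(fix_num)
  out
}

#' @rdname fit_similarity
#' @param x A fitted `similarity_transform`.
#' @param ... Unused.
#' @export
glance.similarity_transform <- function(x, ...) {
  tibble(rotation_deg = x$rotation_deg, scale = x$scale,
         tx = x$translation[1], ty = x$translation[2],
         reflect = x$reflect,
         loss = attr(x, "loss") %||% NA_real_,
         n_px = attr(x, "n_px") %||% NA_integer_)
}

#' Registration loss of a given transform
#'
#' Evaluates the mean squared difference between the warped (float-rendered)
#' moving mask and the fixed mask — the objective [fit_similarity()]
#' minimizes — at an arbitrary transform, e.g. to compare the fitted optimum
#' against a known ground-truth transform.
#'
#' @inheritParams fit_similarity
#' @param transform The transform to evaluate.
#' @return The scalar loss.
#' @export
similarity_loss <- function(moving, fixed, transform, render_sigma = 1.5) {
  mv <- .soft_mask(matrix(as.numeric(moving), nrow(moving)), render_sigma)
  fx <- .soft_mask(matrix(as.numeric(fixed), nrow(fixed)), render_sigma)
  inv <- invert_transform(transform)
  nr <- nrow(fx); nc <- ncol(fx)
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  src <- transform_points(cbind(gx, gy), inv)
  vals <- .sample_bilinear(mv, src[, 1], src[, 2])
  mean((vals - as.numeric(fx))^2)
}

#' Fit a least-squares affine transform to matched landmark points
#'
#' Estimates the affine transform minimizing the summed squared distance
#' between transformed points of set A and their matched points in set B, the
#' procedure used to stack manually identified marker points from two
#' adjacent imaging sections.
#'
#' @param points_a Data frame or matrix of source points (`x`, `y`); at least
#'   3 non-collinear points.
#' @param points_b Matched target points, same size.
#' @return An `affine_transform` with attributes `residuals` (per-point
#'   Euclidean residuals) and `rss`; `tidy()`/`glance()` apply.
#' @export
fit_landmark_affine <- function(points_a, points_b) {
  pa <- if (is.data.frame(points_a)) cbind(points_a$x, points_a$y) else as.matrix(points_a)
  pb <- if (is.data.frame(points_b)) cbind(points_b$x, points_b$y) else as.matrix(points_b)
  if (nrow(pa) != nrow(pb)) abort("Point sets differ in length.")
  if (nrow(pa) < 3) abort("At least 3 landmark pairs are required.")
  X <- cbind(pa, 1)
  if (qr(X)$rank < 3) abort("Landmark points are collinear; the affine fit is degenerate.")
  # two independent least-squares problems, one per output coordinate
  coefs <- qr.solve(X, pb)           # 3 x 2: rows (a, b, t) for x' and y'
  m <- t(coefs)                      # 2 x 3
  out <- affine_transform(m)
  fitted <- X %*% coefs
  res <- sqrt(rowSums((fitted - pb)^2))
  attr(out, "residuals") <- as.numeric(res)
  attr(out, "rss") <- sum((fitted - pb)^2)
  out
}

#' @rdname fit_landmark_affine
#' @param x A fitted `affine_transform`.
#' @param ... Unused.
#' @export
glance.affine_transform <- function(x, ...) {
  r <- attr(x, "residuals")
  tibble(rss = attr(x, "rss") %||% NA_real_,
         rmse = if (is.null(r)) NA_real_ else sqrt(mean(r^2)),
         max_residual = if (is.null(r)) NA_real_ else max(r),
         n_points = if (is.null(r)) NA_integer_ else length(r))
}
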