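#' Ground-truth parameters for a synthetic paired dataset
#'
#' Collects everything the generators need: the cell-type universe and
#' mixing proportions, the true type-by-gene mean expression (`mu_true`)
#' that drives the Poisson spot counts, true type-by-marker protein means,
#' the similarity transform relating the imaging frame to the spot frame,
#' and the expected sequencing depth per spot.
#'
#' `mu_true` is built as a shared baseline plus, for each type, a block of
#' type-specific marker genes with elevated means, so that types are
#' distinguishable and recovery of per-type contributions is well posed.
#' Protein means give every type a strong nuclear (DAPI) signal plus one
#' dominant type-specific marker.
#'
#' @param n_types Number of cell types. Default 4.
#' @param n_genes Number of genes. Default 200.
#' @param type_proportions Probability vector over types; default uniform.
#' @param depth Expected total UMI per spot. Default 2000.
#' @param transform Optional `similarity_transform` (imaging px to spot-frame
#'   um); when `NULL`, [simulate_dataset()] constructs one about the tissue
#'   centre from `rotation_deg`/`scale`/`offset`.
#' @param rotation_deg,scale,offset Parameters used to build the transform
#'   when `transform` is `NULL`.
#' @param marker_block_frac Fraction of genes that are type-specific markers
#'   for each type. Default 0.1.
#' @param seed Integer seed for drawing `mu_true`.
#' @return A `synthetic_truth` list: `cell_types`, `type_proportions`,
#'   `mu_true`, `protein_means`, `markers`, `transform_true`, `depth`,
#'   `seed`.
#' @export
simulate_truth <- function(n_types = 4, n_genes = 200,
                           type_proportions = rep(1 / n_types, n_types),
                           depth = 2000, transform = NULL,
                           rotation_deg = 8, scale = 1, offset = c(12, -9),
                           marker_block_frac = 0.1, seed = 1L) {
  if (abs(sum(type_proportions) - 1) > 1e-12 || any(type_proportions < 0)) {
    abort("`type_proportions` must be nonnegative and sum to 1.")
  }
  if (length(type_proportions) != n_types) {
    abort("`type_proportions` length must equal `n_types`.")
  }
  types <- paste0("type", LETTERS[seq_len(n_types)])
  genes <- sprintf("g%04d", seq_len(n_genes))
  block <- max(1L, floor(n_genes * marker_block_frac))
  mu <- withr::with_seed(seed, {
    m <- matrix(stats::rgamma(n_types * n_genes, shape = 2, rate = 4),
                n_types, n_genes, dimnames = list(types, genes))
    for (k in seq_len(n_types)) {
      hi <- ((k - 1L) * block + seq_len(block) - 1L) %% n_genes + 1L
      m[k, hi] <- m[k, hi] + stats::rgamma(block, shape = 8, rate = 2)
    }
    m
  })
  markers <- c("DAPI", paste0("P_", types))
  pm <- matrix(4, n_types, length(markers), dimnames = list(types, markers))
  pm[, "DAPI"] <- 50
  for (k in seq_len(n_types)) pm[k, paste0("P_", types[k])] <- 40
  structure(list(cell_types = types, type_proportions = type_proportions,
                 mu_true = mu, protein_means = pm, markers = markers,
                 transform_true = transform,
                 transform_spec = list(rotation_deg = rotation_deg,
                                       scale = scale, offset = offset),
                 depth = depth, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a blob-shaped tissue mask
#'
#' Draws a chain of overlapping random disks (each centred near the previous
#' one, so the union is connected), rescales them so the foreground occupies
#' a plausible tissue fraction of the image, and fills any holes. The result
#' is a connected, hole-free foreground occupying 20-80% of the image.
#'
#' @param dim_px Integer `(rows, cols)`, each at least 64.
#' @param n_blobs Number of disks in the chain (>= 1).
#' @param seed Integer seed.
#' @param target_fraction Foreground fraction aimed for. Default 0.4.
#' @return Logical matrix of dimension `dim_px`.
#' @export
simulate_tissue_mask <- function(dim_px, n_blobs = 3, seed = 1L,
                                 target_fraction = 0.4) {
  if (length(dim_px) != 2 || any(dim_px < 64)) {
    abort("`dim_px` must be two integers, each >= 64.")
  }
  if (n_blobs < 1) abort("`n_blobs` must be >= 1.")
  nr <- dim_px[1]; nc <- dim_px[2]
  geom <- withr::with_seed(seed, {
    r_base <- 0.30 * min(nr, nc) / n_blobs^(1 / 3)
    radii <- r_base * runif(n_blobs, 0.8, 1.2)
    cx <- numeric(n_blobs); cy <- numeric(n_blobs)
    cx[1] <- nc / 2; cy[1] <- nr / 2
    if (n_blobs > 1) {
      for (b in 2:n_blobs) {
        ang <- runif(1, 0, 2 * pi)
        d <- 0.7 * (radii[b - 1] + radii[b])
        cx[b] <- cx[b - 1] + d * cos(ang)
        cy[b] <- cy[b - 1] + d * sin(ang)
      }
    }
    list(cx = cx, cy = cy, radii = radii)
  })
  render <- function(s) {
    ccx <- nc / 2 + (geom$cx - nc / 2) * s
    ccy <- nr / 2 + (geom$cy - nr / 2) * s
    rr <- geom$radii * s
    m <- matrix(FALSE, nr, nc)
    px <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    py <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
    for (b in seq_along(rr)) {
      m <- m | ((px - ccx[b])^2 + (py - ccy[b])^2 <= rr[b]^2)
    }
    m
  }
  m <- render(1)
  frac <- mean(m)
  s <- sqrt(target_fraction / frac)
  s <- min(s, 0.95 * min(nr, nc) / (2 * max(abs(geom$cx - nc / 2) +
                                              geom$radii,
                                            abs(geom$cy - nr / 2) +
                                              geom$radii)))
  m <- render(s)
  m <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m * 1)))) > 0)
  if (mean(m) < 0.2 || mean(m) > 0.8) {
    # one corrective rescale toward the target keeps the contract
    s2 <- s * sqrt(target_fraction / mean(m))
    m <- render(s2)
    m <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m * 1)))) > 0)
  }
  m
}

#' Generate cells inside a tissue mask
#'
#' Samples cell positions uniformly over the mask foreground (pixel centres,
#' so each centroid is exactly inside the mask), draws types from the truth
#' proportions, lognormal cell areas, and per-marker protein intensities as
#' multiplicative lognormal noise around the type's protein means (mean
#' preserved; `noise_sdlog = 0` reproduces the means exactly).
#'
#' @param mask Logical tissue mask.
#' @param n_cells Number of cells (>= 1).
#' @param truth A `synthetic_truth`.
#' @param noise_sdlog Lognormal sdlog of the protein noise. Default 0.25.
#' @param area_meanlog,area_sdlog Lognormal parameters of the cell area
#'   (px^2). Defaults `log(80)` and 0.35.
#' @param seed Integer seed.
#' @return Cell table: `cell_id`, `x`, `y` (0-based px), `area`, one column
#'   per marker (true summed intensities), `label` (true type).
#' @export
simulate_cells <- function(mask, n_cells, truth, noise_sdlog = 0.25,
                           area_meanlog = log(80), area_sdlog = 0.35,
                           seed = 1L) {
  fg <- which(mask)
  if (length(fg) == 0) abort("`mask` has no foreground.")
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  nr <- nrow(mask)
  withr::with_seed(seed, {
    idx <- sample(fg, n_cells, replace = n_cells > length(fg))
    y <- (idx - 1L) %% nr
    x <- (idx - 1L) %/% nr
    label <- sample(truth$cell_types, n_cells, replace = TRUE,
                    prob = truth$type_proportions)
    area <- rlnorm(n_cells, area_meanlog, area_sdlog)
    out <- tibble(cell_id = seq_len(n_cells), x = as.numeric(x),
                  y = as.numeric(y), area = area)
    for (m in truth$markers) {
      base <- unname(truth$protein_means[label, m])
      noise <- if (noise_sdlog > 0) {
        rlnorm(n_cells, meanlog = -noise_sdlog^2 / 2, sdlog = noise_sdlog)
      } else rep(1, n_cells)
      out[[m]] <- base * noise
    }
    out$label <- label
    out
  })
}

#' Render cells into a segmentation mask and channel stack
#'
#' Paints each cell as a disk (radius from its area) into a label image,
#' then assigns each channel a constant per-pixel value inside each cell so
#' that the summed channel signal over the cell's painted pixels equals the
#' cell's tabulated marker intensity exactly. Later cells overwrite earlier
#' ones where disks overlap; cells fully occluded are dropped from the
#' images (reported via the `n_rendered` attribute).
#'
#' @param cells A cell table (positions in px).
#' @param dim_px Output image dimension `(rows, cols)`; default fits the
#'   cells with a margin.
#' @param markers Marker columns to render; defaults to [marker_names()].
#' @return List: `label_mask` (integer matrix), `channels` (3D array rows x
#'   cols x markers), `markers`.
#' @export
simulate_cell_image <- function(cells, dim_px = NULL, markers = NULL) {
  markers <- markers %||% marker_names(cells)
  if (is.null(dim_px)) {
    dim_px <- c(ceiling(max(cells$y)) + 16, ceiling(max(cells$x)) + 16)
  }
  nr <- dim_px[1]; nc <- dim_px[2]
  lab <- matrix(0L, nr, nc)
  radius <- pmax(1, sqrt(cells$area / pi))
  for (i in seq_len(nrow(cells))) {
    r0 <- round(cells$y[i]); c0 <- round(cells$x[i])
    rad <- radius[i]
    rs <- max(0, floor(r0 - rad)):min(nr - 1, ceiling(r0 + rad))
    cs <- max(0, floor(c0 - rad)):min(nc - 1, ceiling(c0 + rad))
    sub <- expand.grid(r = rs, c = cs)
    inside <- (sub$r - r0)^2 + (sub$c - c0)^2 <= rad^2
    lab[cbind(sub$r[inside] + 1L, sub$c[inside] + 1L)] <- as.integer(cells$cell_id[i])
  }
  counts <- table(factor(lab[lab > 0], levels = cells$cell_id))
  npix <- as.integer(counts)
  rendered <- npix > 0
  chan <- array(0, dim = c(nr, nc, length(markers)),
                dimnames = list(NULL, NULL, markers))
  pos <- which(lab > 0)
  cell_row <- match(lab[pos], cells$cell_id)
  for (m in seq_along(markers)) {
    per_px <- cells[[markers[m]]][cell_row] / npix[cell_row]
    plane <- matrix(0, nr, nc)
    plane[pos] <- per_px
    chan[, , m] <- plane
  }
  out <- list(label_mask = lab, channels = chan, markers = markers)
  attr(out, "n_rendered") <- sum(rendered)
  out
}

#' Generate spot counts from assigned cells (Poisson mixture)
#'
#' For spot `i` with `n_ik` cells of type `k` (and `n_i` cells in total),
#' gene `j`'s count is Poisson with rate
#' `d_i * sum_k n_ik * mu_norm[k, j]`, where `mu_norm` is `mu_true` with
#' rows normalized to sum to 1 and `d_i = depth / n_i`, so the expected spot
#' total equals `depth` for every occupied spot. Counts are drawn per type
#' and summed, so the realized per-type contribution to every spot is kept
#' as ground truth. Spots with no cells get all-zero rows.
#'
#' @param cells Cell table with `spot_id` (see [assign_cells_to_spots()])
#'   and true `label`.
#' @param truth A `synthetic_truth`.
#' @param spot_ids Spot ids to emit rows for; default: all spots with at
#'   least one assigned cell, sorted.
#' @param seed Integer seed.
#' @return Sparse `dgCMatrix` (spots x genes). Attribute `type_contrib` is a
#'   tibble (`spot_id`, `label`, `true_counts`) of realized per-type totals.
#' @export
simulate_spot_counts <- function(cells, truth, spot_ids = NULL, seed = 1L) {
  mapped <- cells[!is.na(cells$spot_id), , drop = FALSE]
  if (any(is.na(mapped$label))) abort("Every assigned cell needs a true type label.")
  if (!all(mapped$label %in% rownames(truth$mu_true))) {
    abort("`mu_true` does not cover all cell types present.")
  }
  spot_ids <- spot_ids %||% sort(unique(mapped$spot_id))
  genes <- colnames(truth$mu_true)
  mu_norm <- truth$mu_true / rowSums(truth$mu_true)
  N <- table(factor(mapped$spot_id, levels = spot_ids),
             factor(mapped$label, levels = rownames(mu_norm)))
  withr::with_seed(seed, {
    triplets <- vector("list", length(spot_ids))
    contrib <- vector("list", length(spot_ids))
    for (ii in seq_along(spot_ids)) {
      n_i <- sum(N[ii, ])
      if (n_i == 0) next
      d_i <- truth$depth / n_i
      draws <- matrix(0, nrow(mu_norm), length(genes))
      for (k in seq_len(nrow(mu_norm))) {
        if (N[ii, k] == 0) next
        draws[k, ] <- rpois(length(genes), d_i * N[ii, k] * mu_norm[k, ])
      }
      tot <- colSums(draws)
      nz <- which(tot > 0)
      triplets[[ii]] <- cbind(i = rep(ii, length(nz)), j = nz, x = tot[nz])
      contrib[[ii]] <- tibble(spot_id = spot_ids[ii],
                              label = rownames(mu_norm),
                              true_counts = rowSums(draws))
    }
    tr <- do.call(rbind, triplets)
    x <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                              dims = c(length(spot_ids), length(genes)),
                              dimnames = list(spot_ids, genes))
    attr(x, "type_contrib") <- bind_rows(contrib)
    x
  })
}

#' Transformed (and optionally noisy) copy of a cell table
#'
#' Maps positions through a transform and perturbs marker values with
#' additive Gaussian noise truncated at zero — the fixture for the
#' adjacent-section binned-correlation QC.
#'
#' @param cells A cell table.
#' @param transform A `similarity_transform` or `affine_transform`.
#' @param intensity_noise_sd Additive noise sd (same units as the marker
#'   columns). Default 0.
#' @param markers Marker columns to perturb; defaults to [marker_names()].
#' @param seed Integer seed.
#' @return The transformed cell table.
#' @export
simulate_transformed_copy <- function(cells, transform,
                                      intensity_noise_sd = 0,
                                      markers = NULL, seed = 1L) {
  markers <- markers %||% marker_names(cells)
  out <- transform_points(cells, transform)
  if (intensity_noise_sd > 0) {
    out <- withr::with_seed(seed, {
      for (m in markers) {
        out[[m]] <- pmax(0, out[[m]] + rnorm(nrow(out), 0, intensity_noise_sd))
      }
      out
    })
  }
  out
}

#' Simulate a complete paired imaging + sequencing dataset
#'
#' End-to-end generator with full ground truth: a blob tissue mask in the
#' spot (chip) frame, cells with true types and protein intensities,
#' cell-to-spot assignment on the barcode grid, Poisson spot counts, a
#' labelled single-cell reference, the observed imaging section (cell table
#' and rendered label/channel images) in its own rotated/scaled pixel frame,
#' an adjacent imaging section for QC, and six landmark point pairs.
#'
#' The observed imaging frame is related to the chip frame by
#' `truth$transform_true` (built about the tissue centre when not supplied),
#' so that mask-based registration has a known answer.
#'
#' @param layout A [channel_layout()]; default 20x20 spots, 25 um channels
#'   on a 50 um pitch.
#' @param truth A [simulate_truth()]; default 4 types, 200 genes, depth 2000.
#' @param n_cells Number of cells. Default 5000.
#' @param mask_dim Tissue image dimension (px; 1 px = 1 um in the chip
#'   frame). Default covers the grid.
#' @param render_images Render the label mask / channel stack (the slowest
#'   part). Default `TRUE`.
#' @param section_noise_sd Additive protein noise of the adjacent section.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return List with `truth`, `layout`, `mask`, `spots`, `cells` (chip
#'   frame, with `spot_id`), `counts`, `ref_counts`, `ref_labels`,
#'   `cells_obs` (observed imaging frame), `images` (or `NULL`), `cells_b`,
#'   `section_transform`, `landmarks`.
#' @export
simulate_dataset <- function(layout = channel_layout(n_a = 20, n_b = 20,
                                                     channel_width = 25,
                                                     pitch = 50),
                             truth = simulate_truth(),
                             n_cells = 5000, mask_dim = NULL,
                             render_images = TRUE,
                             section_noise_sd = 0.05, seed = 1L) {
  seed <- as.integer(seed)
  extent <- c(layout$n_a, layout$n_b) * layout$pitch
  mask_dim <- mask_dim %||% c(ceiling(extent[2]) + 24, ceiling(extent[1]) + 24)
  mask <- simulate_tissue_mask(mask_dim, n_blobs = 3, seed = seed + 101L)
  cells <- simulate_cells(mask, n_cells, truth, seed = seed + 202L)
  spots <- build_spot_grid(layout)
  cells <- assign_cells_to_spots(cells, spots)
  counts <- simulate_spot_counts(cells, truth, seed = seed + 303L)
  spots$tissue <- spots$spot_id %in% rownames(counts)

  # labelled single-cell reference drawn from the same expression model
  ref <- withr::with_seed(seed + 404L, {
    mu_norm <- truth$mu_true / rowSums(truth$mu_true)
    per_type <- 50L
    labs <- rep(rownames(mu_norm), each = per_type)
    lib <- 5000
    m <- t(vapply(labs, function(k) rpois(ncol(mu_norm), lib * mu_norm[k, ]),
                  numeric(ncol(mu_norm))))
    dimnames(m) <- list(NULL, colnames(mu_norm))
    list(counts = m, labels = labs)
  })

  # observed imaging frame: chip = transform_true(observed)
  if (is.null(truth$transform_true)) {
    ts <- truth$transform_spec
    ctr <- c(mask_dim[2] / 2, mask_dim[1] / 2)
    tmp <- similarity_transform(ts$rotation_deg, ts$scale, c(0, 0))
    A <- transform_matrix(tmp)[, 1:2]
    tr <- ctr + ts$offset - as.numeric(A %*% ctr)
    truth$transform_true <- similarity_transform(ts$rotation_deg, ts$scale, tr)
  }
  inv <- invert_transform(truth$transform_true)
  cells_obs <- transform_points(cells, inv)
  cells_obs$spot_id <- NULL

  images <- NULL
  if (render_images) {
    pad <- 12
    shift <- c(min(cells_obs$x), min(cells_obs$y)) - pad
    # keep the observed frame's coordinates nonnegative for rendering;
    # fold the shift into the ground-truth transform
    if (any(shift < 0)) {
      cells_obs$x <- cells_obs$x - min(0, shift[1])
      cells_obs$y <- cells_obs$y - min(0, shift[2])
      pre <- similarity_transform(0, 1, c(min(0, shift[1]), min(0, shift[2])))
      truth$transform_true <- compose_transforms(pre, truth$transform_true)
    }
    images <- simulate_cell_image(cells_obs, markers = truth$markers)
  }

  section_transform <- similarity_transform(3, 1, c(20, 10))
  cells_b <- simulate_transformed_copy(cells_obs, section_transform,
                                       intensity_noise_sd = section_noise_sd,
                                       markers = truth$markers,
                                       seed = seed + 505L)
  lm_a <- withr::with_seed(seed + 606L, {
    tibble(x = runif(6, min(cells_obs$x), max(cells_obs$x)),
           y = runif(6, min(cells_obs$y), max(cells_obs$y)))
  })
  lm_b <- transform_points(lm_a, section_transform)

  list(truth = truth, layout = layout, mask = mask, spots = spots,
       cells = cells, counts = counts,
       ref_counts = ref$counts, ref_labels = ref$labels,
       cells_obs = cells_obs, images = images, cells_b = cells_b,
       section_transform = section_transform,
       landmarks = list(a = lm_a, b = lm_b))
}
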