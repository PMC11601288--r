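#' Microfluidic channel layout
#'
#' Geometry of the deterministic-barcoding chip: `n_a` x `n_b` channel
#' intersections, each a square spot of side `channel_width` placed on a
#' lattice of spacing `pitch`. Tissue between channels ("dead space") is not
#' covered by any spot.
#'
#' @param n_a,n_b Number of A / B channels. Default 50 each (2,500 spots).
#' @param channel_width Channel (spot) width in micrometres; chips are
#'   typically fabricated at 10, 20, 25 or 50 um.
#' @param pitch Centre-to-centre channel spacing in micrometres. Defaults to
#'   `2 * channel_width` (equal channel and gap widths).
#' @param origin Micrometre xy of spot `(0, 0)`'s centre.
#' @return An object of class `channel_layout`.
#' @export
channel_layout <- function(n_a = 50, n_b = 50, channel_width = 25,
                           pitch = 2 * channel_width, origin = c(0, 0)) {
  if (n_a < 1 || n_b < 1) abort("`n_a` and `n_b` must be >= 1.")
  if (channel_width <= 0 || pitch <= 0 || channel_width > pitch) {
    abort("Require 0 < channel_width <= pitch.")
  }
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 channel_width = channel_width, pitch = pitch,
                 origin = as.numeric(origin)),
            class = "channel_layout")
}

#' Build the barcoded spot table from a channel layout
#'
#' Spot `(i, j)` (0-based indices) is the square of side `channel_width`
#' centred at `origin + (i * pitch, j * pitch)`, with half-open extents
#' `[lo, lo + width)`. Spot ids use the 1-based barcode dialect `"{i}x{j}"`.
#'
#' @param layout A [channel_layout()].
#' @return Tibble with columns `spot_id`, `ai`, `bi` (0-based indices), `x`,
#'   `y` (centre, um), `width`, `tissue` (initialized `NA`; see
#'   [read_gene_spot_matrix()]), carrying the layout as an attribute.
#' @export
build_spot_grid <- function(layout) {
  stopifnot(inherits(layout, "channel_layout"))
  grid <- expand.grid(ai = seq_len(layout$n_a) - 1L,
                      bi = seq_len(layout$n_b) - 1L)
  out <- tibble(
    spot_id = sprintf("%dx%d", grid$ai + 1L, grid$bi + 1L),
    ai = as.integer(grid$ai), bi = as.integer(grid$bi),
    x = layout$origin[1] + grid$ai * layout$pitch,
    y = layout$origin[2] + grid$bi * layout$pitch,
    width = layout$channel_width,
    tissue = NA
  )
  attr(out, "layout") <- layout
  out
}

#' Assign registered cells to barcoded spots
#'
#' A cell belongs to spot `(i, j)` iff its centroid lies inside that spot's
#' half-open square; centroids in the inter-channel dead space (or outside
#' the grid) are unassigned (`NA`). Cells and spots must already share the
#' micrometre spot-frame coordinate system (i.e. after registration and
#' pixel-to-micrometre conversion).
#'
#' @param cells Tibble with `x`, `y` in micrometres.
#' @param spots A spot table from [build_spot_grid()].
#' @return `cells` with a `spot_id` column (`NA` = dead space).
#' @export
assign_cells_to_spots <- function(cells, spots) {
  layout <- attr(spots, "layout")
  if (is.null(layout)) abort("`spots` must carry a `layout` attribute.")
  w <- layout$channel_width; p <- layout$pitch
  relx <- cells$x - (layout$origin[1] - w / 2)
  rely <- cells$y - (layout$origin[2] - w / 2)
  i <- floor(relx / p); j <- floor(rely / p)
  inx <- relx - i * p; iny <- rely - j * p
  ok <- i >= 0 & i < layout$n_a & j >= 0 & j < layout$n_b &
    inx >= 0 & inx < w & iny >= 0 & iny < w
  # bounding box check: the grid's overall footprint
  bb_ok <- cells$x >= layout$origin[1] - p / 2 &
    cells$x < layout$origin[1] + (layout$n_a - 0.5) * p &
    cells$y >= layout$origin[2] - p / 2 &
    cells$y < layout$origin[2] + (layout$n_b - 0.5) * p
  if (nrow(cells) > 0 && !any(bb_ok)) {
    abort(paste0("All cell centroids fall outside the spot grid bounding box; ",
                 "the coordinate frames are probably mismatched (missing ",
                 "registration or px-to-um conversion)."))
  }
  cells$spot_id <- ifelse(ok, sprintf("%dx%d", i + 1, j + 1), NA_character_)
  cells
}

#' Per-spot cell-type composition
#'
#' Computes `beta[i, k]`, the proportion of cells of type `k` among the
#' imaging cells assigned to spot `i`: `beta = n_ik / sum_k n_ik`. Spots with
#' no assigned cells have undefined composition and are simply absent from
#' the table (never zero-filled); unassigned (dead-space) cells are ignored.
#'
#' @param cells Tibble with `spot_id` (from [assign_cells_to_spots()]) and a
#'   `label` column of cell-type names.
#' @param types Optional full type universe; defaults to the labels present.
#'   Types with zero count in a spot get explicit `beta = 0` rows, so each
#'   represented spot has one row per type.
#' @return A tibble of class `spot_composition` with columns `spot_id`,
#'   `label`, `n`, `beta`; attribute `types` carries the type order.
#' @export
compute_composition <- function(cells, types = NULL) {
  if (!"spot_id" %in% names(cells)) abort("`cells` must have a `spot_id` column.")
  if (!"label" %in% names(cells)) abort("`cells` must have a `label` column.")
  mapped <- dplyr::filter(cells, !is.na(.data$spot_id))
  if (any(is.na(mapped$label))) {
    abort("Every cell assigned to a spot must carry a type label.")
  }
  types <- types %||% sort(unique(mapped$label))
  if (!all(mapped$label %in% types)) {
    abort("`types` does not cover all labels present in `cells`.")
  }
  out <- mapped |>
    dplyr::count(.data$spot_id, label = factor(.data$label, levels = types),
                 .drop = FALSE) |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::mutate(beta = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = as.character(.data$label)) |>
    dplyr::arrange(.data$spot_id, match(.data$label, types))
  out <- as_tibble(out)
  attr(out, "types") <- types
  class(out) <- c("spot_composition", class(out))
  out
}

#' Composition as a spots-by-types matrix
#' @param composition A `spot_composition`.
#' @param value `"beta"` (proportions) or `"n"` (counts).
#' @return Numeric matrix, spot ids as rownames, types as colnames.
#' @export
composition_matrix <- function(composition, value = c("beta", "n")) {
  value <- match.arg(value)
  types <- attr(composition, "types")
  wide <- tidyr::pivot_wider(
    as_tibble(composition)[, c("spot_id", "label", value)],
    names_from = "label", values_from = dplyr::all_of(value), values_fill = 0)
  m <- as.matrix(wide[, types, drop = FALSE])
  rownames(m) <- wide$spot_id
  m
}

#' @export
autoplot.spot_composition <- function(object, spots = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(spots)) {
    df <- dplyr::left_join(df, spots[, c("spot_id", "x", "y")], by = "spot_id")
    ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$beta)) +
      geom_tile() +
      scale_fill_viridis_c(limits = c(0, 1)) +
      facet_wrap(~label) +
      coord_equal() +
      labs(x = "x (µm)", y = "y (µm)", fill = "proportion",
           title = "Per-spot cell-type composition") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$label, y = .data$beta)) +
      ggplot2::geom_boxplot() +
      labs(x = NULL, y = "per-spot proportion") +
      theme_minimal()
  }
}
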