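#' Extract per-cell protein features from a segmentation mask and channel stack
#'
#' For every positive label in the segmentation mask, sums each channel's
#' signal over that cell's pixels, and records the pixel-count area and the
#' mean-pixel centroid. Coordinates follow the package convention
#' (x = column, y = row, 0-based pixel centers).
#'
#' @param label_mask 2D integer matrix; 0 = background, positive = cell id.
#' @param channels 3D numeric array (rows x cols x markers), or a list of
#'   matrices, each the same shape as `label_mask`.
#' @param marker_names Character vector naming the channels.
#' @return A cell table: tibble with `cell_id`, `x`, `y`, `area`, and one raw
#'   intensity column per marker.
#' @export
extract_cell_features <- function(label_mask, channels, marker_names) {
  if (is.list(channels)) {
    channels <- array(unlist(channels, use.names = FALSE),
                      dim = c(dim(channels[[1]]), length(channels)))
  }
  if (length(dim(channels)) != 3) abort("`channels` must be a 3D array or list of matrices.")
  if (!all(dim(channels)[1:2] == dim(label_mask))) {
    abort("`label_mask` and `channels` have mismatched shapes.")
  }
  if (dim(channels)[3] != length(marker_names)) {
    abort("`marker_names` length must match the number of channels.")
  }
  lv <- as.integer(label_mask)
  pos <- lv > 0L
  if (!any(pos)) abort("`label_mask` contains no positive labels.")
  ids <- sort(unique(lv[pos]))
  f <- factor(lv[pos], levels = ids)

  nr <- nrow(label_mask)
  idx <- which(pos)                      # column-major linear indices
  px_row <- (idx - 1L) %% nr             # 0-based row = y
  px_col <- (idx - 1L) %/% nr            # 0-based col = x
  area <- as.integer(table(f))
  cx <- tapply(px_col, f, mean)
  cy <- tapply(px_row, f, mean)

  out <- tibble(cell_id = ids, x = as.numeric(cx), y = as.numeric(cy),
                area = area)
  for (m in seq_along(marker_names)) {
    ch <- channels[, , m]
    out[[marker_names[m]]] <- as.numeric(tapply(ch[idx], f, sum))
  }
  out
}

#' Filter cells by size quantiles and nuclear signal
#'
#' Retains cells inside the `[q_low, q_high]` cell-size quantile range
#' (inclusive) whose raw nuclear (DAPI) intensity strictly exceeds its
#' `dapi_quantile` quantile. All quantiles are computed on the input table
#' before any removal, with linear interpolation between order statistics.
#' The defaults — size quantiles (0.05, 0.95), DAPI quantile 0.1 — are the
#' standard filtering settings for this assay.
#'
#' @param cells A cell table (see [extract_cell_features()]).
#' @param dapi_marker Name of the nuclear marker column. Default `"DAPI"`.
#' @param size_quantiles Length-2 numeric, lower/upper area quantiles.
#' @param dapi_quantile Lower quantile of the nuclear signal.
#' @return The filtered cell table. If every cell has identical nuclear
#'   signal the strict threshold would discard all of them; that degenerate
#'   tie is flagged with a warning and the nuclear filter is skipped.
#' @export
filter_cells <- function(cells, dapi_marker = "DAPI",
                         size_quantiles = c(0.05, 0.95),
                         dapi_quantile = 0.1) {
  if (!dapi_marker %in% names(cells)) {
    abort(sprintf("Marker '%s' not found in the cell table.", dapi_marker))
  }
  if (nrow(cells) < 2) abort("Need at least 2 cells to compute quantiles.")
  qa <- quantile(cells$area, size_quantiles, names = FALSE, type = 7)
  qd <- quantile(cells[[dapi_marker]], dapi_quantile, names = FALSE, type = 7)
  keep_size <- cells$area >= qa[1] & cells$area <= qa[2]
  keep_dapi <- cells[[dapi_marker]] > qd
  if (!any(keep_dapi)) {
    warn(paste0("All cells share the same '", dapi_marker, "' intensity; ",
                "the strict nuclear-signal filter would discard every cell ",
                "and is skipped."))
    keep_dapi <- rep(TRUE, nrow(cells))
  }
  cells[keep_size & keep_dapi, , drop = FALSE]
}

#' Quantile-scale per-cell protein features to [0, 1]
#'
#' Optionally divides each cell's raw sums by its area, then maps each
#' marker affinely so its 0.05 quantile goes to 0 and its 0.95 quantile to
#' 1, clipping values outside that range. The anchors are stored so the
#' mapping is reproducible.
#'
#' @param cells A filtered cell table.
#' @param markers Marker columns to scale; defaults to every column other
#'   than `cell_id`, `x`, `y`, `area`, `label`, `spot_id`.
#' @param area_normalize Divide raw sums by cell area before scaling.
#'   Default `TRUE`.
#' @param q_low,q_high Anchor quantiles (default 0.05 and 0.95; linear
#'   interpolation between order statistics).
#' @return A `protein_matrix`: the cell table with marker columns replaced by
#'   scaled values in `[0, 1]`; attribute `anchors` is a tibble of per-marker
#'   `(q_low_value, q_high_value)`. Markers with equal anchors are constant
#'   after scaling (all 0) and flagged with a warning.
#' @export
scale_features <- function(cells, markers = NULL, area_normalize = TRUE,
                           q_low = 0.05, q_high = 0.95) {
  if (q_low >= q_high) abort("`q_low` must be smaller than `q_high`.")
  reserved <- c("cell_id", "x", "y", "area", "label", "spot_id")
  markers <- markers %||% setdiff(names(cells), reserved)
  out <- cells
  anchors <- tibble(marker = markers, lo = NA_real_, hi = NA_real_)
  degenerate <- character(0)
  for (k in seq_along(markers)) {
    m <- markers[k]
    v <- out[[m]]
    if (area_normalize) v <- v / out$area
    qs <- quantile(v, c(q_low, q_high), names = FALSE, type = 7)
    anchors$lo[k] <- qs[1]; anchors$hi[k] <- qs[2]
    if (qs[1] == qs[2]) {
      degenerate <- c(degenerate, m)
      out[[m]] <- rep(0, length(v))
    } else {
      out[[m]] <- pmin(1, pmax(0, (v - qs[1]) / (qs[2] - qs[1])))
    }
  }
  if (length(degenerate) > 0) {
    warn(paste0("Constant marker(s) after normalization (q_low == q_high), ",
                "scaled to all zeros: ", paste(degenerate, collapse = ", ")))
  }
  attr(out, "anchors") <- anchors
  attr(out, "markers") <- markers
  attr(out, "area_normalized") <- area_normalize
  class(out) <- c("protein_matrix", class(out))
  out
}

#' Marker columns of a protein matrix
#' @param x A `protein_matrix` (or any cell table).
#' @return Character vector of marker column names.
#' @export
marker_names <- function(x) {
  attr(x, "markers") %||%
    setdiff(names(x), c("cell_id", "x", "y", "area", "label", "spot_id"))
}
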