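#' Bin cells spatially and average their features
#'
#' Discretizes cell positions into square bins of `bin_size` pixels — a cell
#' at `(x, y)` falls in bin `(floor(y / bin_size), floor(x / bin_size))` —
#' and computes the per-bin mean of each selected feature. Used for
#' cross-section agreement QC after landmark alignment, where ~100 px bins
#' give a few thousand common bins between adjacent sections.
#'
#' @param cells Cell table (in the common coordinate frame).
#' @param markers Feature columns to average; defaults to [marker_names()].
#' @param bin_size Bin side length in pixels. Default 100.
#' @return A `binned_features` tibble: `bin_row`, `bin_col`, `n`, and one
#'   mean column per marker. Empty bins are absent.
#' @export
bin_features <- function(cells, markers = NULL, bin_size = 100) {
  if (nrow(cells) == 0) abort("`cells` is empty; nothing to bin.")
  if (bin_size <= 0) abort("`bin_size` must be positive.")
  markers <- markers %||% marker_names(cells)
  out <- as_tibble(cells) |>
    dplyr::mutate(bin_row = floor(.data$y / bin_size),
                  bin_col = floor(.data$x / bin_size)) |>
    dplyr::group_by(.data$bin_row, .data$bin_col) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(markers), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin_row, .data$bin_col)
  attr(out, "markers") <- markers
  attr(out, "bin_size") <- bin_size
  class(out) <- c("binned_features", class(out))
  out
}

#' Correlate two binned feature tables
#'
#' Identifies the bins common to both tables and computes, for each shared
#' marker, the Pearson correlation of the per-bin means — the agreement
#' statistic for two aligned imaging datasets. Symmetric in its arguments.
#'
#' @param a,b `binned_features` tables ([bin_features()]).
#' @param markers Markers to correlate; defaults to those shared by `a` and
#'   `b`.
#' @return Tibble `marker`, `r`, `n_common`. A marker constant in either
#'   table has undefined correlation: `r = NA` with a warning.
#' @export
correlate_bins <- function(a, b, markers = NULL) {
  markers <- markers %||% intersect(marker_names(a), marker_names(b))
  if (length(markers) == 0) abort("No shared markers to correlate.")
  common <- dplyr::inner_join(as_tibble(a), as_tibble(b),
                              by = c("bin_row", "bin_col"),
                              suffix = c("_a", "_b"))
  if (nrow(common) < 3) {
    abort(sprintf("Only %d common bin(s); need at least 3 for a correlation.",
                  nrow(common)))
  }
  flagged <- character(0)
  res <- purrr::map_dfr(markers, function(m) {
    va <- common[[paste0(m, "_a")]]
    vb <- common[[paste0(m, "_b")]]
    if (sd(va) == 0 || sd(vb) == 0) {
      flagged <<- c(flagged, m)
      tibble(marker = m, r = NA_real_, n_common = nrow(common))
    } else {
      tibble(marker = m, r = cor(va, vb), n_common = nrow(common))
    }
  })
  if (length(flagged) > 0) {
    warn(paste0("Zero-variance marker(s) over common bins, correlation ",
                "undefined: ", paste(flagged, collapse = ", ")))
  }
  res
}

#' Scatter plots of per-bin feature agreement
#'
#' @param a,b `binned_features` tables.
#' @param markers Markers to plot; defaults to the shared set.
#' @return A ggplot, one facet per marker, bin means of `a` against `b`.
#' @export
plot_bin_agreement <- function(a, b, markers = NULL) {
  markers <- markers %||% intersect(marker_names(a), marker_names(b))
  common <- dplyr::inner_join(as_tibble(a), as_tibble(b),
                              by = c("bin_row", "bin_col"),
                              suffix = c("_a", "_b"))
  long <- purrr::map_dfr(markers, function(m) {
    tibble(marker = m, value_a = common[[paste0(m, "_a")]],
           value_b = common[[paste0(m, "_b")]])
  })
  ggplot(long, aes(x = .data$value_a, y = .data$value_b)) +
    geom_point(alpha = 0.4, size = 0.8) +
    facet_wrap(~marker, scales = "free") +
    labs(x = "per-bin mean, dataset A", y = "per-bin mean, dataset B",
         title = "Binned cross-section agreement") +
    theme_minimal()
}
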