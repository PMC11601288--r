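#' Cell-type reference expression profiles
#'
#' Builds `mu[k, j]`, the average expression of gene `j` in cells of type
#' `k`, from a labelled single-cell reference. Each cell is first
#' library-size normalized to a common total (the median cell total by
#' default) so that types with deeper libraries do not dominate the
#' averages; `norm = "raw"` averages the raw counts instead.
#'
#' @param ref_counts Cell-by-gene matrix (dense, sparse, or data frame) with
#'   gene names as column names.
#' @param ref_labels Character vector of per-cell type labels.
#' @param norm `"median"` (library-size normalize each cell to the median
#'   total, then average) or `"raw"`.
#' @return A `reference_profile`: list with `mu` (types x genes matrix) and
#'   `normalization` descriptor.
#' @export
compute_reference_profiles <- function(ref_counts, ref_labels,
                                       norm = c("median", "raw")) {
  norm <- match.arg(norm)
  m <- as.matrix(ref_counts)
  if (length(ref_labels) != nrow(m)) {
    abort("`ref_labels` must have one label per reference cell.")
  }
  if (any(is.na(ref_labels))) abort("Reference labels contain NA.")
  types <- sort(unique(ref_labels))
  if (norm == "median") {
    totals <- rowSums(m)
    if (any(totals == 0)) abort("Reference contains cells with zero total counts.")
    m <- m * (stats::median(totals) / totals)
  }
  mu <- matrix(0, length(types), ncol(m),
               dimnames = list(types, colnames(m)))
  for (k in seq_along(types)) {
    rows <- which(ref_labels == types[k])
    mu[k, ] <- colMeans(m[rows, , drop = FALSE])
  }
  structure(list(mu = mu,
                 normalization = if (norm == "median") "per-cell library-size to median total, then group mean"
                                 else "group mean of raw counts"),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> %d types x %d genes (%s)\n",
              nrow(x$mu), ncol(x$mu), x$normalization))
  invisible(x)
}

#' @rdname compute_reference_profiles
#' @param x A `reference_profile`.
#' @param ... Unused.
#' @export
tidy.reference_profile <- function(x, ...) {
  as_tibble(as.data.frame.table(x$mu, responseName = "mu",
                                stringsAsFactors = FALSE)) |>
    setNames(c("label", "gene", "mu"))
}

#' Split spots into pure-cell-type sub-spots
#'
#' The central deconvolution step: each spot's gene counts are apportioned
#' among the cell types present in it, using the composition measured from
#' the registered imaging cells and a reference expression profile. For spot
#' `i`, gene `j`, type `k`:
#'
#' \deqn{\hat{x}_{i,j,k} = x_{i,j} \cdot
#'   \frac{\beta_{i,k}\,\mu_{k,j}}{\sum_{k'} \beta_{i,k'}\,\mu_{k',j}}}
#'
#' Sub-spots are emitted only for types with `beta > 0`. When the
#' denominator is zero for a gene with positive counts (no type in the spot
#' expresses it in the reference), `fallback = "beta"` (default) distributes
#' the counts proportionally to the composition, preserving the per-spot
#' totals; `fallback = "drop"` zeroes them. Either way the affected genes
#' are recorded in the result's `log`.
#'
#' @param x Spots-by-genes count matrix (dense or `Matrix` sparse) with spot
#'   ids as rownames and gene names as colnames; raw counts are accepted and
#'   the choice is recorded in the output metadata.
#' @param beta A `spot_composition` from [compute_composition()].
#' @param mu A `reference_profile` (or a types-by-genes matrix).
#' @param fallback Zero-denominator policy, `"beta"` or `"drop"`.
#' @return A `subspot_matrix`: list with
#'   * `rna` — sub-spots-by-genes matrix of split expression,
#'   * `meta` — tibble (`subspot_id`, `spot_id`, `label`, `beta`, `n_cells`),
#'   * `log` — tibble of per-gene fallback events and dropped genes/spots,
#'   * `genes`, `types` — the aligned gene and type sets.
#' @export
split_spots <- function(x, beta, mu, fallback = c("beta", "drop")) {
  fallback <- match.arg(fallback)
  if (inherits(mu, "reference_profile")) mu <- mu$mu
  x <- as(as(x, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("`x` needs spot ids as rownames and gene names as colnames.")
  }
  B <- composition_matrix(beta, "beta")
  Ncells <- composition_matrix(beta, "n")
  types <- colnames(B)
  missing_mu <- setdiff(types[colSums(B) > 0], rownames(mu))
  if (length(missing_mu) > 0) {
    abort(paste0("Type(s) present in the composition but absent from the ",
                 "reference profile: ", paste(missing_mu, collapse = ", ")))
  }

  genes <- intersect(colnames(x), colnames(mu))
  dropped_genes <- setdiff(colnames(x), genes)
  spots <- intersect(rownames(x), rownames(B))
  skipped_spots <- setdiff(rownames(x), spots)
  if (length(genes) == 0) abort("No genes shared between `x` and `mu`.")
  if (length(spots) == 0) abort("No spots shared between `x` and the composition.")

  X <- as.matrix(x[spots, genes, drop = FALSE])
  B <- B[spots, types, drop = FALSE]
  M <- mu[types, genes, drop = FALSE]
  D <- B %*% M                                   # spots x genes denominators

  # sub-spot index: (spot, type) pairs with beta > 0, type-major within spot
  pos <- which(t(B) > 0, arr.ind = TRUE)         # rows: (type, spot)
  sub_spot <- spots[pos[, 2]]
  sub_type <- types[pos[, 1]]
  subspot_id <- paste(sub_spot, sub_type, sep = "_")

  zero_den <- D == 0 & X > 0
  rna <- matrix(0, length(subspot_id), length(genes),
                dimnames = list(subspot_id, genes))
  for (r in seq_along(subspot_id)) {
    i <- pos[r, 2]; k <- pos[r, 1]
    w <- B[i, k] * M[k, ] / D[i, ]
    w[D[i, ] == 0] <- if (fallback == "beta") B[i, k] else 0
    vals <- X[i, ] * w
    vals[X[i, ] == 0] <- 0                       # 0 * NaN guard
    rna[r, ] <- vals
  }

  fb_genes <- genes[colSums(zero_den) > 0]
  log <- bind_rows(
    if (length(fb_genes) > 0)
      tibble(event = paste0("zero_denominator_", fallback), item = fb_genes,
             n_spots = colSums(zero_den)[fb_genes]),
    if (length(dropped_genes) > 0)
      tibble(event = "gene_absent_from_reference", item = dropped_genes,
             n_spots = NA_real_),
    if (length(skipped_spots) > 0)
      tibble(event = "spot_without_composition", item = skipped_spots,
             n_spots = NA_real_)
  )
  if (is.null(log) || ncol(log) == 0) {
    log <- tibble(event = character(), item = character(),
                  n_spots = numeric())
  }

  meta <- tibble(subspot_id = subspot_id, spot_id = sub_spot,
                 label = sub_type,
                 beta = B[cbind(pos[, 2], pos[, 1])],
                 n_cells = Ncells[spots, types, drop = FALSE][cbind(pos[, 2], pos[, 1])])
  structure(list(rna = rna, meta = meta, log = log, genes = genes,
                 types = types, counts = "raw", fallback = fallback),
            class = "subspot_matrix")
}

#' @export
print.subspot_matrix <- function(x, ...) {
  cat(sprintf("<subspot_matrix> %d sub-spots (%d spots, %d types) x %d genes; fallback '%s'\n",
              nrow(x$rna), length(unique(x$meta$spot_id)), length(x$types),
              length(x$genes), x$fallback))
  if (nrow(x$log) > 0) cat(sprintf("  %d logged events (see $log)\n", nrow(x$log)))
  invisible(x)
}

#' @rdname split_spots
#' @param x A `subspot_matrix`.
#' @param ... Unused.
#' @export
tidy.subspot_matrix <- function(x, ...) {
  long <- as.data.frame.table(x$rna, responseName = "xhat",
                              stringsAsFactors = FALSE)
  names(long)[1:2] <- c("subspot_id", "gene")
  dplyr::left_join(as_tibble(long), x$meta, by = "subspot_id") |>
    dplyr::select("subspot_id", "spot_id", "label", "gene", "xhat",
                  "beta", "n_cells")
}

#' @rdname split_spots
#' @export
glance.subspot_matrix <- function(x, ...) {
  tibble(n_subspots = nrow(x$rna), n_spots = length(unique(x$meta$spot_id)),
         n_types = length(x$types), n_genes = length(x$genes),
         total_expression = sum(x$rna),
         n_fallback_genes = sum(x$log$event %in%
                                  c("zero_denominator_beta", "zero_denominator_drop")))
}

#' Aggregate scaled protein features into pure-cell-type sub-spots
#'
#' The protein counterpart of [split_spots()]: imaging cells of each type
#' within each spot are averaged into one sub-spot protein vector, placed at
#' the member cells' centroid, with sub-spot ids matching the RNA side.
#'
#' @param cells A `protein_matrix` with `spot_id` and `label` columns (i.e.
#'   scaled, assigned, annotated cells).
#' @param markers Marker columns; defaults to [marker_names()].
#' @return Tibble: `subspot_id`, `spot_id`, `label`, `n_cells`, `x`, `y`,
#'   and one mean scaled intensity column per marker. Spot/type combinations
#'   with no cells are simply absent.
#' @export
aggregate_protein_subspots <- function(cells, markers = NULL) {
  markers <- markers %||% marker_names(cells)
  mapped <- dplyr::filter(as_tibble(cells), !is.na(.data$spot_id))
  if (any(is.na(mapped$label))) abort("All assigned cells must be labelled.")
  mapped |>
    dplyr::group_by(.data$spot_id, .data$label) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     x = mean(.data$x), y = mean(.data$y),
                     dplyr::across(dplyr::all_of(markers), mean),
                     .groups = "drop") |>
    dplyr::mutate(subspot_id = paste(.data$spot_id, .data$label, sep = "_"),
                  .before = 1)
}

#' Export matched RNA / protein sub-spot matrices for multimodal analysis
#'
#' Writes the paired inputs consumed by weighted-nearest-neighbour style
#' multimodal integration: the split RNA matrix (MatrixMarket + sidecars),
#' the matched protein aggregates (CSV), and sub-spot metadata (CSV), with
#' identical row order across the three. Sub-spots lacking a protein partner
#' (no imaging cell of that type in the spot) are excluded and counted.
#'
#' @param subspots A `subspot_matrix`.
#' @param proteins Output of [aggregate_protein_subspots()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a report tibble: rows written, RNA-only rows dropped,
#'   protein-only rows dropped.
#' @export
export_wnn_inputs <- function(subspots, proteins, dir) {
  stopifnot(inherits(subspots, "subspot_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shared <- intersect(rownames(subspots$rna), proteins$subspot_id)
  if (length(shared) == 0) abort("No sub-spots shared between RNA and protein tables.")
  rna <- subspots$rna[shared, , drop = FALSE]
  prot <- proteins[match(shared, proteins$subspot_id), , drop = FALSE]
  meta <- subspots$meta[match(shared, subspots$meta$subspot_id), , drop = FALSE]
  meta <- dplyr::left_join(meta, prot[, c("subspot_id", "x", "y", "n_cells")],
                           by = "subspot_id")
  if (!identical(prot$subspot_id, rownames(rna)) ||
      !identical(meta$subspot_id, rownames(rna))) {
    abort("Internal row-order mismatch while pairing sub-spot matrices.")
  }
  write_gene_spot_matrix(Matrix::Matrix(rna, sparse = TRUE), dir,
                         barcode_col = rownames(rna))
  readr::write_csv(prot, file.path(dir, "protein.csv"))
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  report <- tibble(n_written = length(shared),
                   n_rna_only = nrow(subspots$rna) - length(shared),
                   n_protein_only = nrow(proteins) - length(shared))
  invisible(report)
}
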