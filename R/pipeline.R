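# File-level pipeline stages. Each stage reads and writes only declared
# files under its data/output directories, so the CLI subcommands and
# `run-all` are thin wrappers and outputs are reproducible from config +
# seed (timestamps go to the log only, never into data files).

.log_line <- function(config, msg, log_path = NULL) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  config_hash(config), msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

#' Simulate a dataset to disk
#'
#' Writes a complete synthetic paired dataset in the pipeline's exchange
#' formats: segmentation + channel TIFFs, spot counts and reference as
#' MatrixMarket trios, adjacent-section cell table, landmark pairs, pivot
#' labels, and the ground-truth parameters as YAML.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory.
#' @param log_path Optional run log file.
#' @return Invisibly, the in-memory dataset (see [simulate_dataset()]).
#' @export
stage_simulate <- function(config, dir, log_path = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$simulate
  truth <- simulate_truth(n_types = sc$n_types, n_genes = sc$n_genes,
                          depth = sc$depth, seed = config$seed)
  ds <- simulate_dataset(layout = config_layout(config), truth = truth,
                         n_cells = sc$n_cells,
                         section_noise_sd = sc$section_noise_sd,
                         seed = config$seed)
  write_image_tiff(ds$images$label_mask, file.path(dir, "label_mask.tif"))
  write_image_tiff(ds$images$channels, file.path(dir, "channels.tif"),
                   page_names = ds$images$markers)
  write_gene_spot_matrix(ds$counts, file.path(dir, "counts"))
  write_gene_spot_matrix(Matrix::Matrix(ds$ref_counts, sparse = TRUE),
                         file.path(dir, "reference"),
                         barcode_col = sprintf("cell%04d",
                                               seq_len(nrow(ds$ref_counts))))
  readr::write_tsv(tibble(label = ds$ref_labels),
                   file.path(dir, "reference", "labels.tsv"),
                   col_names = FALSE)
  write_cell_table(ds$cells_b, file.path(dir, "cells_section_b.csv"))
  write_landmarks_csv(ds$landmarks, file.path(dir, "landmarks.csv"))
  pivots <- withr::with_seed(config$seed + 707L, {
    n <- nrow(ds$cells_obs)
    idx <- sample(n, max(10L, round(sc$pivot_fraction * n)))
    tibble(cell_id = ds$cells_obs$cell_id[idx],
           label = ds$cells_obs$label[idx])
  })
  readr::write_csv(pivots, file.path(dir, "pivots.csv"))
  tt <- ds$truth$transform_true
  yaml::write_yaml(list(cell_types = ds$truth$cell_types,
                        type_proportions = ds$truth$type_proportions,
                        depth = ds$truth$depth,
                        markers = ds$truth$markers,
                        transform_true = list(rotation_deg = tt$rotation_deg,
                                              scale = tt$scale,
                                              tx = tt$translation[1],
                                              ty = tt$translation[2]),
                        seed = ds$truth$seed),
                   file.path(dir, "truth.yaml"))
  write_config_yaml(config, file.path(dir, "config.yaml"))
  .log_line(config, sprintf("simulate: %d cells, %d tissue spots -> %s",
                            nrow(ds$cells_obs), sum(ds$spots$tissue), dir),
            log_path)
  invisible(ds)
}

#' Preprocess the imaging data on disk
#'
#' Extracts per-cell features from the label mask and channel stack, applies
#' the size/nuclear-signal filter, quantile-scales markers, and writes the
#' scaled cell table plus the scaling anchors.
#'
#' @inheritParams stage_simulate
#' @param data_dir Directory produced by [stage_simulate()] (or containing
#'   equivalently named inputs).
#' @param out_dir Output directory.
#' @return Invisibly, the scaled `protein_matrix`.
#' @export
stage_preprocess <- function(config, data_dir, out_dir, log_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pc <- config$preprocess
  lab <- read_image_tiff(file.path(data_dir, "label_mask.tif"))
  chan <- read_image_tiff(file.path(data_dir, "channels.tif"))
  cells <- extract_cell_features(lab, chan, dimnames(chan)[[3]])
  n_raw <- nrow(cells)
  cells <- filter_cells(cells, dapi_marker = pc$dapi_marker,
                        size_quantiles = c(pc$q_low, pc$q_high),
                        dapi_quantile = pc$dapi_quantile)
  scaled <- scale_features(cells, area_normalize = pc$area_normalize,
                           q_low = pc$q_low, q_high = pc$q_high)
  write_cell_table(scaled, file.path(out_dir, "cells_scaled.csv"))
  anchors <- attr(scaled, "anchors")
  yaml::write_yaml(list(marker = anchors$marker, lo = anchors$lo,
                        hi = anchors$hi,
                        area_normalized = pc$area_normalize),
                   file.path(out_dir, "scaling_anchors.yaml"))
  .log_line(config, sprintf("preprocess: %d cells extracted, %d retained",
                            n_raw, nrow(scaled)), log_path)
  attr(scaled, "n_raw") <- n_raw
  invisible(scaled)
}

#' Register the imaging frame onto the spot grid
#'
#' Detects the tissue boundary on the nuclear channel, rasterizes the
#' tissue-covered spots, fits the similarity transform, and writes it (plus
#' the raster's pixel-to-micrometre metadata) as YAML.
#'
#' @inheritParams stage_preprocess
#' @return Invisibly, a list with `transform`, `raster`, `spots`.
#' @export
stage_register <- function(config, data_dir, out_dir, log_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chan <- read_image_tiff(file.path(data_dir, "channels.tif"))
  dapi <- chan[, , config$preprocess$dapi_marker]
  boundary <- detect_tissue_boundary(dapi, sigma_px = config$registration$sigma_px)
  counts <- read_gene_spot_matrix(file.path(data_dir, "counts"))
  spots <- flag_tissue_spots(build_spot_grid(config_layout(config)), counts)
  raster <- rasterize_spot_mask(spots,
                                px_per_pitch = config$registration$px_per_pitch)
  tf <- fit_similarity(boundary, solidify_spot_mask(raster),
                       allow_reflection = config$registration$allow_reflection)
  write_transform_yaml(tf, file.path(out_dir, "transform.yaml"))
  yaml::write_yaml(list(um_per_px = attr(raster, "um_per_px"),
                        origin_um = as.numeric(attr(raster, "origin_um"))),
                  file.path(out_dir, "raster_meta.yaml"))
  .log_line(config, sprintf(
    "register: rotation %.3f deg, scale %.4f, t=(%.2f, %.2f), loss %.3g",
    tf$rotation_deg, tf$scale, tf$translation[1], tf$translation[2],
    attr(tf, "loss")), log_path)
  invisible(list(transform = tf, raster = raster, spots = spots))
}

#' Assign and annotate registered cells
#'
#' Maps scaled cell positions through the fitted transform into the
#' micrometre spot frame, assigns each cell to its spot (or to dead space),
#' trains the pivot-seeded label classifier and annotates every cell, and
#' writes the assigned, labelled cell table.
#'
#' @inheritParams stage_preprocess
#' @return Invisibly, a list with the annotated `cells` and the
#'   `label_classifier`.
#' @export
stage_assign <- function(config, data_dir, out_dir, log_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scaled <- read_cell_table(file.path(out_dir, "cells_scaled.csv"))
  tf <- read_transform_yaml(file.path(out_dir, "transform.yaml"))
  rmeta <- yaml::read_yaml(file.path(out_dir, "raster_meta.yaml"))
  counts <- read_gene_spot_matrix(file.path(data_dir, "counts"))
  spots <- flag_tissue_spots(build_spot_grid(config_layout(config)), counts)

  reg <- transform_points(scaled, tf)                   # raster px frame
  reg$x <- rmeta$origin_um[1] + reg$x * rmeta$um_per_px # -> um spot frame
  reg$y <- rmeta$origin_um[2] + reg$y * rmeta$um_per_px
  reg <- assign_cells_to_spots(reg, spots)

  pivots <- readr::read_csv(file.path(data_dir, "pivots.csv"),
                            show_col_types = FALSE, progress = FALSE)
  pivots <- dplyr::semi_join(pivots, reg, by = "cell_id")
  markers <- setdiff(names(scaled), c("cell_id", "x", "y", "area", "label",
                                      "spot_id"))
  piv_rows <- reg[match(pivots$cell_id, reg$cell_id), , drop = FALSE]
  clf <- train_label_classifier(piv_rows, pivots$label, markers = markers,
                                seed = config$seed)
  pred <- predict_labels(clf, reg)
  reg$label <- pred$label
  reg$label[match(pivots$cell_id, reg$cell_id)] <- pivots$label
  # keep the scaled positions too: QC runs in the imaging frame
  write_cell_table(reg, file.path(out_dir, "cells_assigned.csv"))
  .log_line(config, sprintf(
    "assign: %d/%d cells in spots; classifier holdout accuracy %.3f",
    sum(!is.na(reg$spot_id)), nrow(reg), clf$holdout_accuracy), log_path)
  invisible(list(cells = reg, classifier = clf))
}

#' Split spots into pure-cell-type sub-spots on disk
#'
#' Builds the reference profiles, computes per-spot composition from the
#' assigned cells, splits the counts, aggregates the matched protein
#' sub-spots, checks count conservation, and writes the paired sub-spot
#' matrices.
#'
#' @inheritParams stage_preprocess
#' @return Invisibly, a list with `subspots`, `proteins`, `composition`,
#'   `conservation`.
#' @export
stage_split <- function(config, data_dir, out_dir, log_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- read_cell_table(file.path(out_dir, "cells_assigned.csv"))
  counts <- read_gene_spot_matrix(file.path(data_dir, "counts"))
  ref <- read_gene_spot_matrix(file.path(data_dir, "reference"),
                               dialect = NULL)
  ref_labels <- readr::read_tsv(file.path(data_dir, "reference", "labels.tsv"),
                                col_names = "label", show_col_types = FALSE,
                                progress = FALSE)$label
  mu <- compute_reference_profiles(ref, ref_labels)
  comp <- compute_composition(cells)
  min_cells <- config$split$min_cells_per_spot
  if (min_cells > 1) {
    keep <- comp |>
      dplyr::group_by(.data$spot_id) |>
      dplyr::summarise(tot = sum(.data$n)) |>
      dplyr::filter(.data$tot >= min_cells)
    comp <- comp[comp$spot_id %in% keep$spot_id, , drop = FALSE]
  }
  sub <- split_spots(counts, comp, mu, fallback = config$split$fallback)
  prot <- aggregate_protein_subspots(cells)
  cons <- check_conservation(sub, counts)
  export_wnn_inputs(sub, prot, file.path(out_dir, "wnn"))
  readr::write_csv(as_tibble(comp), file.path(out_dir, "composition.csv"))
  .log_line(config, sprintf(
    "split: %d spots -> %d sub-spots; conservation max rel err %.3g (%s)",
    length(unique(sub$meta$spot_id)), nrow(sub$rna), cons$max_rel_err,
    if (cons$pass) "pass" else "FAIL"), log_path)
  invisible(list(subspots = sub, proteins = prot, composition = comp,
                 conservation = cons))
}

#' Cross-section agreement QC on disk
#'
#' Fits the landmark affine mapping section B onto section A, bins both
#' cell tables, correlates the per-bin marker means, and writes the
#' per-marker correlation table.
#'
#' @inheritParams stage_preprocess
#' @return Invisibly, the correlation tibble.
#' @export
stage_qc <- function(config, data_dir, out_dir, log_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells_a <- read_cell_table(file.path(out_dir, "cells_scaled.csv"))
  cells_b <- read_cell_table(file.path(data_dir, "cells_section_b.csv"))
  # section B arrives raw: apply the same filtering and scaling as section A
  pc <- config$preprocess
  cells_b <- filter_cells(cells_b, dapi_marker = pc$dapi_marker,
                          size_quantiles = c(pc$q_low, pc$q_high),
                          dapi_quantile = pc$dapi_quantile)
  cells_b <- scale_features(cells_b, area_normalize = pc$area_normalize,
                            q_low = pc$q_low, q_high = pc$q_high)
  lm <- read_landmarks_csv(file.path(data_dir, "landmarks.csv"))
  aff <- fit_landmark_affine(lm$b, lm$a)   # B -> A common frame
  cells_b <- transform_points(cells_b, aff)
  markers <- intersect(marker_names(cells_a), marker_names(cells_b))
  bin_a <- bin_features(cells_a, markers, bin_size = config$qc$bin_size)
  bin_b <- bin_features(cells_b, markers, bin_size = config$qc$bin_size)
  res <- correlate_bins(bin_a, bin_b, markers)
  readr::write_csv(res, file.path(out_dir, "qc_correlations.csv"))
  .log_line(config, sprintf("qc: %d markers, median r %.3f over %d bins",
                            nrow(res), stats::median(res$r, na.rm = TRUE),
                            res$n_common[1]), log_path)
  invisible(res)
}

#' Check count conservation of a spot splitting
#'
#' Verifies that within each spot and gene the sub-spot expression sums back
#' to the observed count (for genes the splitting covered), the defining
#' invariant of the closed-form split.
#'
#' @param subspots A `subspot_matrix`.
#' @param x The original spots-by-genes counts.
#' @param tol Relative tolerance. Default 1e-9.
#' @return List: `max_rel_err`, `n_checked`, `pass`.
#' @export
check_conservation <- function(subspots, x, tol = 1e-9) {
  genes <- subspots$genes
  spots <- unique(subspots$meta$spot_id)
  X <- as.matrix(x[spots, genes, drop = FALSE])
  S <- rowsum(subspots$rna, group = subspots$meta$spot_id)[spots, , drop = FALSE]
  # drop genes the splitting explicitly zeroed (fallback = "drop")
  if (subspots$fallback == "drop") {
    dropped <- subspots$log$item[subspots$log$event == "zero_denominator_drop"]
    keep <- setdiff(genes, dropped)
    X <- X[, keep, drop = FALSE]; S <- S[, keep, drop = FALSE]
  }
  denom <- pmax(X, 1)
  rel <- abs(S - X) / denom
  list(max_rel_err = max(rel), n_checked = length(rel),
       pass = max(rel) <= tol)
}

#' Run the full pipeline end to end
#'
#' Chains preprocess, register, assign, split and QC over a simulated (or
#' equivalently structured) dataset directory and writes a machine-readable
#' `report.json` summarizing cell filtering, registration, splitting, the
#' conservation check, and the QC correlations.
#'
#' @inheritParams stage_preprocess
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, data_dir, out_dir, log_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scaled <- stage_preprocess(config, data_dir, out_dir, log_path)
  reg <- stage_register(config, data_dir, out_dir, log_path)
  asg <- stage_assign(config, data_dir, out_dir, log_path)
  spl <- stage_split(config, data_dir, out_dir, log_path)
  qc <- stage_qc(config, data_dir, out_dir, log_path)
  report <- list(
    config_hash = config_hash(config),
    n_cells_extracted = attr(scaled, "n_raw"),
    n_cells_retained = nrow(scaled),
    registration = list(rotation_deg = reg$transform$rotation_deg,
                        scale = reg$transform$scale,
                        tx = reg$transform$translation[1],
                        ty = reg$transform$translation[2],
                        loss = attr(reg$transform, "loss")),
    n_cells_in_spots = sum(!is.na(asg$cells$spot_id)),
    classifier_holdout_accuracy = asg$classifier$holdout_accuracy,
    n_spots_split = length(unique(spl$subspots$meta$spot_id)),
    n_subspots = nrow(spl$subspots$rna),
    conservation = spl$conservation,
    qc_correlations = setNames(as.list(qc$r), qc$marker)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(config, sprintf("run-all complete; conservation %s",
                            if (spl$conservation$pass) "pass" else "FAIL"),
            log_path)
  invisible(report)
}
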