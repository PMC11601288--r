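#' Read a gene-by-spot matrix (MatrixMarket + sidecars)
#'
#' Reads the 10x-style trio — `matrix.mtx` (genes in rows on disk),
#' `features.tsv`, `barcodes.tsv` — and returns the matrix oriented
#' spots-by-genes. Barcodes are parsed to barcode-grid indices with the
#' configurable dialect (default `"{i}x{j}"`, 1-based); spots present in the
#' file are the tissue-covered spots.
#'
#' @param dir Directory containing the trio, or `NULL` to pass the three
#'   paths explicitly.
#' @param mtx,features,barcodes Explicit file paths (override `dir`).
#' @param dialect Regular expression with two capture groups extracting the
#'   A/B indices from a barcode. Set to `NULL` to skip grid parsing (e.g.
#'   for sub-spot matrices).
#' @return Sparse `dgCMatrix`, spots x genes, rownames = barcodes, colnames
#'   = features; attribute `grid_index` is a tibble (`spot_id`, `ai`, `bi`,
#'   0-based) when `dialect` applies.
#' @export
read_gene_spot_matrix <- function(dir = NULL, mtx = NULL, features = NULL,
                                  barcodes = NULL,
                                  dialect = "^(\\d+)x(\\d+)$") {
  if (!is.null(dir)) {
    mtx <- mtx %||% file.path(dir, "matrix.mtx")
    features <- features %||% file.path(dir, "features.tsv")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
  }
  for (p in c(mtx, features, barcodes)) {
    if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) abort(sprintf(
                  "Malformed MatrixMarket file '%s': %s", mtx,
                  conditionMessage(e))))
  feats <- readr::read_tsv(features, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
  bcs <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(feats) != nrow(m)) {
    abort(sprintf("features.tsv has %d rows but the matrix has %d gene rows.",
                  nrow(feats), nrow(m)))
  }
  if (nrow(bcs) != ncol(m)) {
    abort(sprintf("barcodes.tsv has %d rows but the matrix has %d spot columns.",
                  nrow(bcs), ncol(m)))
  }
  x <- Matrix::t(m)
  x <- as(as(x, "CsparseMatrix"), "generalMatrix")
  rownames(x) <- bcs[[1]]
  colnames(x) <- feats[[1]]
  if (!is.null(dialect)) {
    hit <- regmatches(bcs[[1]], regexec(dialect, bcs[[1]]))
    bad <- which(vapply(hit, length, integer(1)) != 3)
    if (length(bad) > 0) {
      abort(sprintf(
        "Barcode '%s' (barcodes.tsv line %d) does not match the grid dialect '%s'.",
        bcs[[1]][bad[1]], bad[1], dialect))
    }
    attr(x, "grid_index") <- tibble(
      spot_id = bcs[[1]],
      ai = vapply(hit, function(h) as.integer(h[2]), integer(1)) - 1L,
      bi = vapply(hit, function(h) as.integer(h[3]), integer(1)) - 1L)
  }
  x
}

#' Write a gene-by-spot matrix (MatrixMarket + sidecars)
#'
#' Inverse of [read_gene_spot_matrix()]: the spots-by-genes matrix is
#' transposed to genes-in-rows on disk.
#'
#' @param x Spots-by-genes matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param barcode_col Barcodes to write; default `rownames(x)`.
#' @return Invisibly, `dir`.
#' @export
write_gene_spot_matrix <- function(x, dir, barcode_col = rownames(x)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(Matrix::Matrix(x, sparse = TRUE))
  Matrix::writeMM(as(m, "generalMatrix"), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = colnames(x)), file.path(dir, "features.tsv"),
                   col_names = FALSE)
  readr::write_tsv(tibble(barcode = barcode_col),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(dir)
}

#' Flag tissue-covered spots from a gene-spot matrix
#'
#' Spots present in the sequencing output are tissue-covered; spots absent
#' from it are not.
#'
#' @param spots A spot table.
#' @param x A spots-by-genes matrix (its rownames are the covered spots).
#' @return `spots` with the `tissue` column set.
#' @export
flag_tissue_spots <- function(spots, x) {
  spots$tissue <- spots$spot_id %in% rownames(x)
  spots
}

#' Read / write a cell table as CSV
#'
#' Columns: `cell_id`, `x`, `y`, `area`, one column per marker, optional
#' `label` and `spot_id`. Round-trips float values at full precision.
#'
#' @param cells Cell table.
#' @param path CSV path.
#' @return `read_cell_table()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_cell_table <- function(cells, path) {
  df <- as_tibble(cells)
  # %.17g representations round-trip doubles exactly through the CSV
  dbl <- vapply(df, is.double, logical(1))
  df[dbl] <- lapply(df[dbl], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  # base strtod parsing is correctly rounded, so %.17g values round-trip
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("cell_id", "x", "y", "area")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0("Cell table '", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

#' Read / write images as multi-page TIFF with a YAML sidecar
#'
#' Pages are stored as 32-bit floats rescaled to `[0, 1]`; the per-page
#' scale factors and page names live in a `<path>.yaml` sidecar so values
#' are restored on read (exactly for binary and integer label masks, to
#' float precision otherwise).
#'
#' @param image A matrix (mask), or a 3D array / list of matrices (stack).
#' @param path TIFF path.
#' @param page_names Optional page (marker) names stored in the sidecar.
#' @return The reader returns a matrix (single page) or a 3D array with
#'   page names as the third dimnames; the writer returns `path` invisibly.
#' @export
write_image_tiff <- function(image, path, page_names = NULL) {
  pages <- if (is.list(image)) image
           else if (length(dim(image)) == 3) {
             lapply(seq_len(dim(image)[3]), function(k) image[, , k])
           } else list(image)
  is_int <- vapply(pages, function(p) is.logical(p) || is.integer(p) ||
                     all(p == round(p)), logical(1))
  scales <- vapply(pages, function(p) max(1, max(as.numeric(p))), numeric(1))
  scaled <- lapply(seq_along(pages), function(k) {
    matrix(as.numeric(pages[[k]]) / scales[k], nrow(pages[[k]]))
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  yaml::write_yaml(list(pages = page_names %||% paste0("page", seq_along(pages)),
                        scales = as.numeric(scales),
                        integer = as.logical(is_int)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else
    list(pages = paste0("page", seq_along(pages)),
         scales = rep(1, length(pages)),
         integer = rep(FALSE, length(pages)))
  out <- lapply(seq_along(pages), function(k) {
    v <- pages[[k]] * meta$scales[k]
    if (isTRUE(meta$integer[k])) v <- round(v)
    v
  })
  if (length(out) == 1) return(out[[1]])
  arr <- array(unlist(out), dim = c(dim(out[[1]]), length(out)),
               dimnames = list(NULL, NULL, meta$pages))
  arr
}

#' Read landmark point pairs from CSV
#'
#' Expects columns `ax`, `ay`, `bx`, `by` — one row per matched point pair.
#'
#' @param path CSV path.
#' @return List of two tibbles `a` and `b`, each with `x`, `y`.
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ax", "ay", "bx", "by")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Landmarks file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  list(a = tibble(x = df$ax, y = df$ay), b = tibble(x = df$bx, y = df$by))
}

#' @rdname read_landmarks_csv
#' @param landmarks List with point tables `a` and `b`.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  readr::write_csv(tibble(ax = landmarks$a$x, ay = landmarks$a$y,
                          bx = landmarks$b$x, by = landmarks$b$y), path)
  invisible(path)
}

# Pipeline configuration ------------------------------------------------------

.config_defaults <- function() {
  list(
    layout = list(n_a = 20L, n_b = 20L, channel_width = 25, pitch = 50,
                  origin_x = 0, origin_y = 0),
    registration = list(sigma_px = 5, allow_reflection = FALSE,
                        px_per_pitch = 10, um_per_px = 1),
    preprocess = list(q_low = 0.05, q_high = 0.95, dapi_quantile = 0.1,
                      dapi_marker = "DAPI", area_normalize = TRUE),
    split = list(fallback = "beta", min_cells_per_spot = 1L),
    qc = list(bin_size = 100),
    simulate = list(n_types = 4L, n_genes = 200L, depth = 2000,
                    n_cells = 5000L, section_noise_sd = 0.05,
                    pivot_fraction = 0.1),
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' Builds, validates and (de)serializes the configuration consumed by the
#' pipeline stages. Unknown keys at either level are rejected.
#'
#' @param ... Named overrides of the defaults, nested as in the default
#'   list (e.g. `layout = list(n_a = 10)`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  for (sec in names(over)) {
    if (is.list(cfg[[sec]])) {
      bad2 <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
      if (length(bad2) > 0) {
        abort(paste0("Unknown configuration key(s) in '", sec, "': ",
                     paste(bad2, collapse = ", ")))
      }
      cfg[[sec]][names(over[[sec]])] <- over[[sec]]
    } else {
      cfg[[sec]] <- over[[sec]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a pipeline configuration
#' @param config A `pipeline_config`.
#' @return Short character hash identifying the configuration.
#' @export
config_hash <- function(config) {
  substr(digest::digest(unclass(config), algo = "sha256"), 1, 12)
}

#' Layout object from a configuration
#' @param config A `pipeline_config`.
#' @return A [channel_layout()].
#' @export
config_layout <- function(config) {
  l <- config$layout
  channel_layout(n_a = l$n_a, n_b = l$n_b, channel_width = l$channel_width,
                 pitch = l$pitch, origin = c(l$origin_x, l$origin_y))
}
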