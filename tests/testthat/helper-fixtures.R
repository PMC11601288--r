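# Shared fixture builders. Everything is generated in code under fixed
# seeds; no files are read.

tiny_truth <- function(n_types = 2, n_genes = 20, seed = 42L, ...) {
  simulate_truth(n_types = n_types, n_genes = n_genes, seed = seed, ...)
}

# a small cell table with arbitrary marker values (no simulation)
make_cells <- function(n, markers = c("DAPI", "CD3"), seed = 1L) {
  withr::with_seed(seed, {
    out <- tibble::tibble(cell_id = seq_len(n),
                          x = runif(n, 0, 500), y = runif(n, 0, 400),
                          area = exp(rnorm(n, log(80), 0.3)))
    for (m in markers) out[[m]] <- exp(rnorm(n, log(50), 0.5))
    out
  })
}

# composition built from an explicit list of (spot, label) cells
make_composition <- function(labels_by_spot, types = NULL) {
  cells <- tibble::tibble(
    spot_id = rep(names(labels_by_spot), lengths(labels_by_spot)),
    label = unlist(labels_by_spot, use.names = FALSE))
  compute_composition(cells, types = types)
}

# a filled disk mask
disk_mask <- function(dim_px, center, radius) {
  px <- matrix(rep(seq_len(dim_px[2]) - 1, each = dim_px[1]), dim_px[1])
  py <- matrix(rep(seq_len(dim_px[1]) - 1, times = dim_px[2]), dim_px[1])
  (px - center[1])^2 + (py - center[2])^2 <= radius^2
}

# number of connected foreground components (8-connectivity)
n_components <- function(mask) {
  max(EBImage::bwlabel(EBImage::Image(t(mask * 1))))
}

# small simulated dataset shared by deconvolution/pipeline tests
small_dataset <- function(seed = 11L, n_cells = 1500, n_genes = 100) {
  simulate_dataset(
    layout = channel_layout(n_a = 10, n_b = 10, channel_width = 25, pitch = 50),
    truth = simulate_truth(n_types = 3, n_genes = n_genes, seed = seed),
    n_cells = n_cells, render_images = FALSE, seed = seed)
}
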