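# Shared fixture builders; everything is generated in code at test time.

path_graph <- function(n, labels = NULL) {
  spatial_graph(cbind(seq_len(n - 1L), 2:n), n, labels)
}

cycle_graph <- function(n) {
  spatial_graph(rbind(cbind(seq_len(n - 1L), 2:n), c(n, 1L)), n)
}

random_graph <- function(n, p_edge = 0.4) {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  suppressWarnings(spatial_graph(pairs[keep, , drop = FALSE], n))
}

# grid of unit squares written as a shapefile; returns the .shp path
write_square_grid_shapefile <- function(dir, rows, cols, stem = "grid",
                                        label_field = "NAME") {
  polys <- list()
  labels <- character(0)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    x0 <- c - 1; y0 <- r - 1
    polys[[length(polys) + 1L]] <-
      list(cbind(x = c(x0, x0 + 1, x0 + 1, x0, x0),
                 y = c(y0, y0, y0 + 1, y0 + 1, y0)))
    labels <- c(labels, sprintf("sq_r%d_c%d", r, c))
  }
  icarlap:::write_shapefile(file.path(dir, stem), polys, labels, label_field)
}

# small synthetic stand-in for a county case study: shapefile + R data
# script with y / E vectors (optionally with a label vector and shuffled
# row order)
write_synthetic_case_study <- function(dir, rows = 2, cols = 3,
                                       with_labels = FALSE, shuffle = FALSE,
                                       seed = 42) {
  set.seed(seed)
  shp <- write_square_grid_shapefile(dir, rows, cols, stem = "mississippi_county")
  n <- rows * cols
  labels <- sprintf("sq_r%d_c%d", rep(seq_len(rows), each = cols),
                    rep(seq_len(cols), rows))
  E <- round(stats::runif(n, 0.5, 3), 3)
  y <- stats::rpois(n, E)
  ord <- if (shuffle) sample(n) else seq_len(n)
  lines <- c(
    "# synthetic case study data (generated by the test-suite)",
    sprintf("observed <- c(%s)", paste(y[ord], collapse = ", ")),
    sprintf("expected <- c(%s)", paste(E[ord], collapse = ", ")))
  if (with_labels)
    lines <- c(lines, sprintf("county <- c(%s)",
                              paste(sprintf('"%s"', labels[ord]), collapse = ", ")))
  writeLines(lines, file.path(dir, "ms_human_wv_data.R"))
  list(dir = dir, shp = shp, y = y, E = E, labels = labels, order = ord)
}
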