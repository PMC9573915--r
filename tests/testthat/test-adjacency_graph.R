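test_that("edges_to_graph builds W, D_w, Q with the expected structure", {
  g <- edges_to_graph(cbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_equal(g$n_regions, 3L)
  expect_equal(as.integer(diag(as.matrix(g$D_w))), c(1L, 2L, 1L))
  expect_equal(as.matrix(g$Q),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  # duplicate edge (including reversed orientation) collapses to one
  g2 <- edges_to_graph(cbind(c("A", "B"), c("B", "A")), c("A", "B"))
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(as.integer(diag(as.matrix(g2$D_w))), c(1L, 1L))
})

test_that("edges_to_graph rejects bad input", {
  expect_error(edges_to_graph(cbind("A", "Z"), c("A", "B")), "not found")
  expect_error(edges_to_graph(cbind("A", "A"), c("A", "B")), "[Ss]elf")
  expect_error(spatial_graph(rbind(c(1L, 5L)), 3L), "1..n_regions")
})

test_that("connected components partition the regions", {
  g <- edges_to_graph(cbind(c("A", "C"), c("B", "D")), c("A", "B", "C", "D"))
  comps <- connected_components(g)
  expect_length(comps, 2L)
  expect_equal(g$n_components, 2L)
  expect_equal(sort(unname(unlist(comps))), 1:4)
  expect_length(connected_components(path_graph(3)), 1L)
})

test_that("W symmetry, Q row sums and eigenstructure hold on random graphs", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:12, 1L)
    g <- random_graph(n)
    W <- as.matrix(g$W)
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W %in% c(0, 1)))
    Q <- as.matrix(g$Q)
    expect_equal(rowSums(Q), rep(0, n), tolerance = 1e-12)
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
    expect_equal(sum(abs(ev) < 1e-8), g$n_components)
    # quadratic form equals the pairwise-difference sum
    s <- rnorm(n)
    pairwise <- sum((s[g$edges[, 1]] - s[g$edges[, 2]])^2)
    expect_equal(icar_quadratic(s, g), pairwise, tolerance = 1e-12)
  }
})

test_that("plain and GAL edge list files round-trip through read_edge_list", {
  labs <- c("A", "B", "C", "D")
  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "A B", "B,C", "C D"), plain)
  g <- edges_to_graph(plain, labs)
  expect_equal(nrow(g$edges), 3L)
  gal <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("4", "A 1", "B", "B 2", "A C", "C 2", "B D", "D 1", "C"), gal)
  g2 <- edges_to_graph(read_edge_list(gal), labs)
  expect_equal(g2$edges, g$edges)
  expect_error(read_edge_list(withr::local_tempfile()), "not found")
})

test_that("queen and rook contiguity on a 2x2 grid of unit squares", {
  dir <- withr::local_tempdir()
  shp <- write_square_grid_shapefile(dir, 2, 2)
  gq <- polygons_to_graph(shp, "queen")
  # all squares share at least a corner: complete graph, degrees 3
  expect_equal(nrow(gq$edges), 6L)
  expect_equal(as.integer(diag(as.matrix(gq$D_w))), rep(3L, 4L))
  gr <- polygons_to_graph(shp, "rook")
  # corners excluded: 4 edges, degrees 2
  expect_equal(nrow(gr$edges), 4L)
  expect_equal(as.integer(diag(as.matrix(gr$D_w))), rep(2L, 4L))
  # queen edge set contains the rook edge set
  key <- function(e) paste(e[, 1], e[, 2])
  expect_true(all(key(gr$edges) %in% key(gq$edges)))
})

test_that("queen contains rook on larger grids and labels follow record order", {
  dir <- withr::local_tempdir()
  shp <- write_square_grid_shapefile(dir, 3, 4)
  gq <- polygons_to_graph(shp, "queen")
  gr <- polygons_to_graph(shp, "rook")
  key <- function(e) paste(e[, 1], e[, 2])
  expect_true(all(key(gr$edges) %in% key(gq$edges)))
  expect_equal(gq$region_labels[1:4],
               c("sq_r1_c1", "sq_r1_c2", "sq_r1_c3", "sq_r1_c4"))
  # rook on a grid matches the lattice constructor
  glat <- lattice_graph(3, 4, "rook")
  expect_equal(nrow(gr$edges), nrow(glat$edges))
  expect_equal(as.integer(diag(as.matrix(gr$D_w))),
               as.integer(diag(as.matrix(glat$D_w))))
})

test_that("zero-neighbour polygons are reported as their own component", {
  dir <- withr::local_tempdir()
  # two touching squares plus one far-away island
  polys <- list(
    list(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))),
    list(cbind(c(1, 2, 2, 1, 1), c(0, 0, 1, 1, 0))),
    list(cbind(c(10, 11, 11, 10, 10), c(0, 0, 1, 1, 0))))
  stem <- file.path(dir, "island")
  icarlap:::write_shapefile(stem, polys, c("a", "b", "island"))
  expect_warning(g <- polygons_to_graph(paste0(stem, ".shp")), "zero neighbours")
  expect_equal(g$n_components, 2L)
  expect_equal(as.integer(diag(as.matrix(g$D_w))), c(1L, 1L, 0L))
})

test_that("missing or malformed shapefiles raise input errors", {
  expect_error(polygons_to_graph("/nonexistent/file.shp"), "not found")
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.shp")
  writeBin(as.raw(1:64), bad)
  writeBin(as.raw(1:64), file.path(dir, "bad.dbf"))
  expect_error(polygons_to_graph(bad), "unreadable")
})

test_that("graph audit files are written and consistent", {
  g <- path_graph(4, c("w", "x", "y", "z"))
  dir <- withr::local_tempdir()
  out <- write_graph_audit(g, file.path(dir, "edges.csv"),
                           file.path(dir, "degrees.csv"))
  ed <- read.csv(file.path(dir, "edges.csv"))
  dg <- read.csv(file.path(dir, "degrees.csv"))
  expect_equal(nrow(ed), 3L)
  expect_equal(dg$degree, c(1L, 2L, 2L, 1L))
  expect_equal(dg$region_label, c("w", "x", "y", "z"))
})
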