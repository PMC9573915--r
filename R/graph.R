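#' Spatial contiguity graph
#'
#' A `spatial_graph` holds the first-order contiguity structure used by the
#' intrinsic CAR model: the binary symmetric weight matrix \eqn{W}, the
#' diagonal degree matrix \eqn{D_w} (whose entries \eqn{n_i} count the
#' first-order neighbours of region \eqn{i}), and the singular structure
#' matrix \eqn{Q = D_w - W}.  \eqn{Q 1 = 0} by construction, so
#' \eqn{\mathrm{rank}(Q) = n - k} where \eqn{k} is the number of connected
#' components.
#'
#' @param edges integer matrix with two columns, one row per undirected
#'   edge (1-based region indices).  Duplicates and orientation are
#'   collapsed; self-loops are an error.
#' @param n_regions number of regions (vertices).
#' @param region_labels character vector of length `n_regions`; defaults to
#'   `"1"`, ..., `"n"`.
#' @return an object of class `spatial_graph` with fields `n_regions`,
#'   `edges`, `W`, `D_w`, `Q` (sparse, from the Matrix package),
#'   `components` (integer component membership), `n_components`, and
#'   `region_labels`.
#' @examples
#' g <- spatial_graph(rbind(c(1, 2), c(2, 3)), 3, c("A", "B", "C"))
#' g$Q  # tridiagonal path-graph structure matrix
#' @export
spatial_graph <- function(edges, n_regions, region_labels = NULL) {
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 1L)
    stop("n_regions must be a positive integer")
  if (is.null(region_labels)) region_labels <- as.character(seq_len(n_regions))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != n_regions)
    stop("region_labels must have length n_regions")
  if (anyDuplicated(region_labels))
    stop("region_labels must be unique")

  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (any(is.na(edges)) || any(edges < 1L) || any(edges > n_regions))
    stop("edge indices must lie in 1..n_regions")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-pairs are not allowed in a contiguity graph")
  # canonical order i < j, collapse duplicates
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]

  W <- Matrix::sparseMatrix(
    i = c(edges[, 1L], edges[, 2L]),
    j = c(edges[, 2L], edges[, 1L]),
    x = 1,
    dims = c(n_regions, n_regions),
    symmetric = FALSE
  )
  deg <- as.numeric(Matrix::rowSums(W))
  D_w <- Matrix::Diagonal(n_regions, deg)
  Q <- methods::as(D_w - W, "symmetricMatrix")

  comp <- graph_components(edges, n_regions)
  isolated <- which(deg == 0)
  if (length(isolated) > 0L)
    warning(sprintf(
      "%d region(s) with zero neighbours (own component, latent effect fixed at 0): %s",
      length(isolated), paste(region_labels[isolated], collapse = ", ")))

  structure(
    list(n_regions = n_regions, edges = edges, W = W, D_w = D_w, Q = Q,
         components = comp, n_components = max(comp),
         region_labels = region_labels,
         # reference-semantics cache for per-graph decompositions (eigen,
         # sum-to-zero basis, log pseudo-determinant); survives copies
         cache = new.env(parent = emptyenv())),
    class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d regions, %d edges, %d connected component(s)\n",
              x$n_regions, nrow(x$edges), x$n_components))
  cat(sprintf("  degrees: min %d, median %s, max %d\n",
              as.integer(min(graph_degrees(x))),
              format(stats::median(graph_degrees(x))),
              as.integer(max(graph_degrees(x)))))
  invisible(x)
}

graph_degrees <- function(graph) as.numeric(Matrix::diag(graph$D_w))

# breadth-first search component labelling; edges as canonical 2-col matrix
graph_components <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  label <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    label <- label + 1L
    queue <- start
    comp[start] <- label
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- label
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

#' Connected components of a contiguity graph
#'
#' @param graph a [spatial_graph()].
#' @return list of integer index vectors, one per component, in order of
#'   first appearance.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  split(seq_len(graph$n_regions), graph$components)
}

#' Build a contiguity graph from an explicit edge list
#'
#' @param edge_list two-column matrix or data.frame of region labels (one
#'   row per undirected neighbour pair), or a character path to a plain
#'   two-column text file or a GAL neighbour-list file (see
#'   [read_edge_list()]).
#' @param labels ordered character vector of all region labels; fixes the
#'   vertex order of the graph.
#' @return a [spatial_graph()].
#' @examples
#' edges_to_graph(cbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
#' @export
edges_to_graph <- function(edge_list, labels) {
  labels <- as.character(labels)
  if (is.character(edge_list) && length(edge_list) == 1L && file.exists(edge_list))
    edge_list <- read_edge_list(edge_list)
  pairs <- as.matrix(edge_list)
  if (ncol(pairs) != 2L) stop("edge_list must have two columns")
  storage.mode(pairs) <- "character"
  unknown <- setdiff(unique(as.vector(pairs)), labels)
  if (length(unknown) > 0L)
    stop("edge labels not found among region labels: ",
         paste(unknown, collapse = ", "))
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("self-pairs are not allowed in a contiguity graph")
  idx <- cbind(match(pairs[, 1L], labels), match(pairs[, 2L], labels))
  spatial_graph(idx, length(labels), labels)
}

#' Read an edge list file
#'
#' Two dialects are supported and auto-detected: a plain two-column text
#' file (whitespace or comma separated, one undirected edge per line,
#' `#` comments allowed) and a GAL neighbour list (header line with the
#' region count, then alternating `label n_neighbours` / neighbour lines).
#'
#' @param path file path.
#' @param dialect `"auto"`, `"plain"` or `"gal"`.
#' @return two-column character matrix of label pairs.
#' @export
read_edge_list <- function(path, dialect = c("auto", "plain", "gal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("edge list file is empty: ", path)
  toks <- lapply(lines, function(l) strsplit(l, "[,[:space:]]+")[[1L]])
  if (dialect == "auto") {
    # GAL files start with a 1- or 4-token numeric header; plain files have
    # two tokens per line throughout.
    first <- toks[[1L]]
    dialect <- if (all(lengths(toks) == 2L)) "plain"
               else if (all(!is.na(suppressWarnings(as.numeric(first))))) "gal"
               else stop("cannot determine edge list dialect of ", path)
  }
  if (dialect == "plain") {
    if (!all(lengths(toks) == 2L))
      stop("plain edge list must have exactly two columns per line")
    return(do.call(rbind, toks))
  }
  # GAL: drop header, then pairs of (label n) / neighbour lines
  toks <- toks[-1L]
  out <- list()
  i <- 1L
  while (i < length(toks)) {
    head <- toks[[i]]
    if (length(head) != 2L)
      stop("malformed GAL record at line ", i + 1L)
    lab <- head[[1L]]
    nn <- as.integer(head[[2L]])
    nbrs <- if (nn == 0L) character(0) else toks[[i + 1L]]
    if (length(nbrs) != nn)
      stop("GAL record for ", lab, " announces ", nn,
           " neighbours but lists ", length(nbrs))
    if (nn > 0L) out[[length(out) + 1L]] <- cbind(lab, nbrs)
    i <- i + if (nn == 0L) 1L else 2L
  }
  do.call(rbind, out)
}

#' Write the derived edge list and degree table for audit
#'
#' @param graph a [spatial_graph()].
#' @param edges_csv,degrees_csv output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, a list with the two data frames written.
#' @export
write_graph_audit <- function(graph, edges_csv = NULL, degrees_csv = NULL) {
  stopifnot(inherits(graph, "spatial_graph"))
  lab <- graph$region_labels
  ed <- data.frame(from = lab[graph$edges[, 1L]],
                   to = lab[graph$edges[, 2L]],
                   stringsAsFactors = FALSE)
  dg <- data.frame(region_label = lab,
                   degree = as.integer(graph_degrees(graph)),
                   component = graph$components,
                   stringsAsFactors = FALSE)
  if (!is.null(edges_csv)) utils::write.csv(ed, edges_csv, row.names = FALSE)
  if (!is.null(degrees_csv)) utils::write.csv(dg, degrees_csv, row.names = FALSE)
  invisible(list(edges = ed, degrees = dg))
}
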