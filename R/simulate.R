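#' Rectangular lattice contiguity graph
#'
#' @param rows,cols lattice dimensions (at least 2x2 cells overall).
#' @param contiguity_rule `"rook"` (4-neighbour, default) or `"queen"`
#'   (8-neighbour).
#' @return a [spatial_graph()] with labels `"r<i>c<j>"` in row-major
#'   order.
#' @export
lattice_graph <- function(rows, cols, contiguity_rule = c("rook", "queen")) {
  contiguity_rule <- match.arg(contiguity_rule)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 4L) stop("lattice must have at least 4 cells")
  idx <- function(r, c) (r - 1L) * cols + c
  edges <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < rows) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
    if (contiguity_rule == "queen") {
      if (r < rows && c < cols)
        edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c + 1L))
      if (r < rows && c > 1L)
        edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c - 1L))
    }
  }
  labels <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                              function(r, c) sprintf("r%dc%d", r, c))))
  spatial_graph(do.call(rbind, edges), rows * cols, labels)
}

#' Draw an ICAR field on the sum-to-zero subspace
#'
#' Samples \eqn{s} from the proper Gaussian with precision \eqn{Q/\tau^2}
#' restricted to the per-component sum-to-zero subspace, by the spectral
#' construction \eqn{s = \tau \sum_{\ell: \lambda_\ell > 0} v_\ell
#' z_\ell/\sqrt{\lambda_\ell}} with \eqn{z_\ell} iid standard normal.
#' Component sums are zero exactly (to rounding), not merely in
#' expectation.
#'
#' @param graph a [spatial_graph()] with at most 5000 regions (dense
#'   eigendecomposition guard).
#' @param tau_scale dispersion \eqn{\tau \ge 0} on the scale of the
#'   quadratic form \eqn{s'Qs/(2\tau^2)}; `0` returns the zero field.
#' @param seed optional integer seed.
#' @return numeric latent field of length `n_regions`.
#' @export
sample_icar_field <- function(graph, tau_scale, seed = NULL) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (!is.finite(tau_scale) || tau_scale < 0) stop("tau_scale must be >= 0")
  if (graph$n_regions > 5000L)
    stop("n_regions > 5000: dense eigendecomposition guard; use a sparse sampler")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- graph$n_regions
  if (tau_scale == 0) return(numeric(n))
  eig <- graph_eigen(graph)
  r <- n - graph$n_components
  if (r == 0L) return(numeric(n))
  vals <- eig$values[seq_len(r)]
  vecs <- eig$vectors[, seq_len(r), drop = FALSE]
  z <- stats::rnorm(r)
  drop(vecs %*% (tau_scale * z / sqrt(vals)))
}

#' Simulation configuration
#'
#' Describes a synthetic Poisson-ICAR world: lattice (or explicit graph),
#' true parameters, offsets, and covariate generation.  Defaults match
#' the package's reference recovery scenario: a 15x15 rook lattice,
#' \eqn{\beta_0 = 0.5}, \eqn{\tau = 0.5}, constant offsets \eqn{E = 50}.
#'
#' @param lattice_shape `c(rows, cols)` or an explicit [spatial_graph()].
#' @param contiguity_rule `"rook"` or `"queen"` (lattice construction).
#' @param true_beta0 intercept.
#' @param true_beta covariate coefficients (length sets the number of
#'   standard-normal covariate columns unless `covariate_spec` overrides).
#' @param true_tau_scale \eqn{\tau \ge 0} on the quadratic-form scale.
#' @param offsets positive scalar (broadcast) or per-region vector.
#' @param covariate_spec function `(n, p, ...)` returning an `n x p`
#'   matrix; default iid standard normal columns.
#' @param seed integer seed (default 1).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(lattice_shape = c(15L, 15L),
                       contiguity_rule = c("rook", "queen"),
                       true_beta0 = 0.5, true_beta = numeric(0),
                       true_tau_scale = 0.5, offsets = 50,
                       covariate_spec = NULL, seed = 1L) {
  contiguity_rule <- match.arg(contiguity_rule)
  if (!inherits(lattice_shape, "spatial_graph")) {
    lattice_shape <- as.integer(lattice_shape)
    if (length(lattice_shape) != 2L || any(is.na(lattice_shape)))
      stop("lattice_shape must be c(rows, cols) or a spatial_graph")
    if (prod(lattice_shape) < 4L) stop("lattice must have at least 4 cells")
  }
  if (!is.finite(true_tau_scale) || true_tau_scale < 0)
    stop("true_tau_scale must be >= 0")
  if (any(!is.finite(offsets)) || any(offsets <= 0))
    stop("offsets must be positive")
  if (is.null(covariate_spec))
    covariate_spec <- function(n, p) matrix(stats::rnorm(n * p), n, p)
  structure(list(lattice_shape = lattice_shape,
                 contiguity_rule = contiguity_rule,
                 true_beta0 = as.numeric(true_beta0),
                 true_beta = as.numeric(true_beta),
                 true_tau_scale = as.numeric(true_tau_scale),
                 offsets = as.numeric(offsets),
                 covariate_spec = covariate_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate counts from the Poisson-ICAR generative model
#'
#' Builds the lattice graph, draws covariates and the ICAR field, sets
#' \eqn{\lambda = \exp(\beta_0 + X\beta + s)} and draws
#' \eqn{y_i \sim \mathrm{Pois}(E_i \lambda_i)}.
#'
#' @param config a [sim_config()].
#' @return a [model_data()]; the ground truth (field, risks, parameters)
#'   is attached as `attr(, "truth")`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  graph <- if (inherits(config$lattice_shape, "spatial_graph"))
    config$lattice_shape
  else
    lattice_graph(config$lattice_shape[1L], config$lattice_shape[2L],
                  config$contiguity_rule)
  n <- graph$n_regions
  set.seed(config$seed)
  p <- length(config$true_beta)
  X <- if (p > 0L) config$covariate_spec(n, p) else NULL
  s <- sample_icar_field(graph, config$true_tau_scale)  # uses current RNG state
  E <- rep_len(config$offsets, n)
  lp <- config$true_beta0 + (if (p > 0L) drop(X %*% config$true_beta) else 0) + s
  lambda <- exp(lp)
  y <- stats::rpois(n, E * lambda)
  out <- model_data(y, E, graph, X)
  attr(out, "truth") <- list(s = s, lambda = lambda,
                             params = icar_params(config$true_beta0,
                                                  config$true_beta,
                                                  log(max(config$true_tau_scale,
                                                          .Machine$double.xmin))),
                             tau_scale = config$true_tau_scale,
                             config = config)
  out
}
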