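#' Bind areal count data to a contiguity graph
#'
#' The Poisson-ICAR model for small-area disease counts is
#' \deqn{y_i \sim \mathrm{Pois}(E_i \lambda_i), \quad
#'       \log \lambda_i = \beta_0 + \sum_j \beta_j x_{ij} + s_i,}
#' where \eqn{E_i > 0} is the expected count (offset) of region \eqn{i},
#' \eqn{\lambda_i} the relative risk, and \eqn{s} an intrinsic CAR field
#' on the contiguity graph.  `model_data` validates and packages the
#' observed pieces.
#'
#' @param y nonnegative integer counts, one per region.
#' @param E positive expected counts / offsets, one per region.
#' @param graph a [spatial_graph()].
#' @param X optional numeric covariate matrix, `n_regions` rows.
#' @return object of class `model_data` with fields `y`, `E`, `X`, `graph`.
#' @export
model_data <- function(y, E, graph, X = NULL) {
  stopifnot(inherits(graph, "spatial_graph"))
  n <- graph$n_regions
  y <- as.numeric(y); E <- as.numeric(E)
  if (length(y) != n || length(E) != n)
    stop(sprintf("y and E must have length n_regions = %d", n))
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("y must be finite nonnegative integer counts")
  if (any(!is.finite(E)) || any(E <= 0))
    stop("all offsets E must be positive")
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    rownames(X) <- NULL
    if (nrow(X) != n) stop("X must have n_regions rows")
    if (any(!is.finite(X))) stop("X must be finite")
  }
  structure(list(y = y, E = E, X = X, graph = graph), class = "model_data")
}

#' @export
print.model_data <- function(x, ...) {
  cat(sprintf("model_data: %d regions, %d covariate(s), total y = %d, total E = %.3f\n",
              x$graph$n_regions, ncol(x$X), as.integer(sum(x$y)), sum(x$E)))
  invisible(x)
}

#' Assemble model data from a CSV joined to a graph by region label
#'
#' @param csv path to a CSV (or a data.frame) with columns for the region
#'   label, counts, offsets, and any covariates.
#' @param graph a [spatial_graph()]; its `region_labels` define the join
#'   keys and the row order of the result.
#' @param label_col,y_col,E_col column names.
#' @param covariates character vector of covariate column names (optional).
#' @return a [model_data()] aligned with graph order.  Any label present
#'   in only one of the two sources is a hard error listing the unmatched
#'   labels.
#' @export
model_data_from_csv <- function(csv, graph, label_col = "region_label",
                                y_col = "y", E_col = "E",
                                covariates = NULL) {
  df <- if (is.data.frame(csv)) csv else utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c(label_col, y_col, E_col, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s) in data: ", paste(miss, collapse = ", "))
  lab <- as.character(df[[label_col]])
  only_data <- setdiff(lab, graph$region_labels)
  only_graph <- setdiff(graph$region_labels, lab)
  if (length(only_data) > 0L || length(only_graph) > 0L)
    stop("label mismatch between data and graph.",
         if (length(only_data)) paste0(" In data only: ",
                                       paste(only_data, collapse = ", "), "."),
         if (length(only_graph)) paste0(" In graph only: ",
                                        paste(only_graph, collapse = ", "), "."))
  ord <- match(graph$region_labels, lab)
  X <- if (length(covariates) > 0L)
    as.matrix(df[ord, covariates, drop = FALSE]) else NULL
  model_data(df[[y_col]][ord], df[[E_col]][ord], graph, X)
}

#' Model parameters
#'
#' \eqn{\theta = (\beta_0, \beta, \log\tau)} with the spatial dispersion
#' parameterized on the unconstrained log scale; \eqn{\tau} enters the
#' ICAR quadratic form as \eqn{s' Q s / (2\tau^2)}, so \eqn{\tau^2} is the
#' variance-scale quantity (\eqn{\sigma_s^2}) with conditional variances
#' \eqn{\tau^2 / n_i}.
#'
#' @param beta0 intercept.
#' @param beta covariate coefficients (may be length 0).
#' @param log_tau log of the spatial dispersion \eqn{\tau}.
#' @return object of class `icar_params`.
#' @export
icar_params <- function(beta0 = 0, beta = numeric(0), log_tau = 0) {
  beta0 <- as.numeric(beta0); beta <- as.numeric(beta)
  log_tau <- as.numeric(log_tau)
  if (!all(is.finite(c(beta0, beta, log_tau))))
    stop("all parameters must be finite")
  structure(list(beta0 = beta0, beta = beta, log_tau = log_tau),
            class = "icar_params")
}

params_to_vec <- function(params) {
  v <- c(beta0 = params$beta0)
  if (length(params$beta) > 0L)
    v <- c(v, stats::setNames(params$beta, paste0("beta", seq_along(params$beta))))
  c(v, log_tau = params$log_tau)
}

vec_to_params <- function(theta, p) {
  icar_params(beta0 = theta[[1L]],
              beta = if (p > 0L) theta[1L + seq_len(p)] else numeric(0),
              log_tau = theta[[length(theta)]])
}

#' Linear predictor
#'
#' \eqn{\eta_i = \log E_i + \beta_0 + \sum_j \beta_j x_{ij} + s_i}.
#'
#' @param data a [model_data()].
#' @param params an [icar_params()].
#' @param s latent spatial field (numeric, length `n_regions`).
#' @return numeric vector \eqn{\eta}.
#' @export
linear_predictor <- function(data, params, s) {
  nu <- latent_shift(data, params, s)
  log(data$E) + nu
}

# beta0 + X beta + s, shared by several operations
latent_shift <- function(data, params, s) {
  n <- data$graph$n_regions
  s <- as.numeric(s)
  if (length(s) != n) stop("latent field s must have length n_regions")
  if (length(params$beta) != ncol(data$X))
    stop(sprintf("params carry %d coefficients but data has %d covariates",
                 length(params$beta), ncol(data$X)))
  drop(params$beta0 + if (ncol(data$X) > 0L) data$X %*% params$beta else 0) + s
}

#' ICAR quadratic form
#'
#' \eqn{s' Q s = \sum_{(i,j) \in E} (s_i - s_j)^2} with \eqn{Q = D_w - W}.
#'
#' @inheritParams linear_predictor
#' @param graph a [spatial_graph()].
#' @return nonnegative scalar.
#' @export
icar_quadratic <- function(s, graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  s <- as.numeric(s)
  if (length(s) != graph$n_regions) stop("length(s) must equal n_regions")
  as.numeric(t(s) %*% (graph$Q %*% s))
}

# log pseudo-determinant of Q and positive-eigenpair basis, cached per graph
graph_eigen <- function(graph) {
  cache <- graph$cache
  if (is.null(cache$eig)) {
    if (graph$n_regions > 5000L)
      stop("dense eigendecomposition guard: n_regions > 5000")
    cache$eig <- eigen(as.matrix(graph$Q), symmetric = TRUE)
  }
  cache$eig
}

graph_log_pdet <- function(graph) {
  cache <- graph$cache
  if (is.null(cache$log_pdet)) {
    eig <- graph_eigen(graph)
    r <- graph$n_regions - graph$n_components
    vals <- eig$values[seq_len(r)]  # eigen() sorts decreasing
    if (r > 0L && min(vals) <= 0)
      stop("Q has fewer positive eigenvalues than n - k; graph is inconsistent")
    cache$log_pdet <- sum(log(vals))
  }
  cache$log_pdet
}

# tau-dependent generalized normalizing constant of the ICAR log-density on
# the per-component sum-to-zero subspace (rank n - k)
icar_log_normconst <- function(graph, log_tau) {
  r <- graph$n_regions - graph$n_components
  -(r / 2) * log(2 * pi) + 0.5 * graph_log_pdet(graph) - r * log_tau
}

#' ICAR log-density
#'
#' Unnormalized mode returns \eqn{-s'Qs/(2\tau^2)}.  Normalized mode adds
#' the generalized normalizing constant
#' \eqn{-\frac{n-k}{2}\log 2\pi + \frac12 \log \mathrm{pdet}(Q) - (n-k)\log\tau},
#' where pdet is the product of the \eqn{n-k} positive eigenvalues of the
#' singular structure matrix \eqn{Q} and \eqn{k} the number of connected
#' components; the result is then a proper density on the per-component
#' sum-to-zero subspace.
#'
#' @inheritParams icar_quadratic
#' @param log_tau log spatial dispersion.
#' @param normalized include the normalizing constant?
#' @return scalar log-density.
#' @export
icar_log_density <- function(s, graph, log_tau, normalized = TRUE) {
  s <- as.numeric(s)
  if (any(!is.finite(s))) stop("latent field s must be finite")
  tau2 <- exp(2 * log_tau)
  val <- -icar_quadratic(s, graph) / (2 * tau2)
  if (normalized) val <- val + icar_log_normconst(graph, log_tau)
  val
}

#' Joint negative log-likelihood of the Poisson-ICAR model
#'
#' \deqn{\mathrm{nll}(\theta, s) = -\sum_i \{ y_i \eta_i - E_i e^{\beta_0 +
#'   x_i'\beta + s_i} \} + \frac{s'Qs}{2\tau^2} \; (-\; c(\tau)
#'   \text{ if normalized}),}
#' where \eqn{c(\tau)} is the ICAR normalizing constant of
#' [icar_log_density()].  The data-constant \eqn{\log(y_i!)} is omitted
#' throughout, so values differ from the full Poisson negative
#' log-likelihood by a constant that does not affect estimation.
#'
#' @inheritParams linear_predictor
#' @param normalized include the \eqn{\tau}-dependent ICAR normalizing
#'   constant (default `TRUE`; required for finite dispersion MLEs).
#' @return scalar.
#' @export
joint_nll <- function(data, params, s, normalized = TRUE) {
  nu <- latent_shift(data, params, s)
  mu <- data$E * exp(nu)
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu))[1L]
    stop(sprintf("overflow in exp(eta) at region index %d (eta = %.3f)",
                 bad, log(data$E[bad]) + nu[bad]))
  }
  eta <- log(data$E) + nu
  val <- -sum(data$y * eta - mu) +
    icar_quadratic(s, data$graph) / (2 * exp(2 * params$log_tau))
  if (normalized) val <- val - icar_log_normconst(data$graph, params$log_tau)
  val
}

#' Relative risk
#'
#' \eqn{\lambda_i = \exp(\beta_0 + x_i'\beta + s_i)}; the fitted mean
#' count is \eqn{E_i \lambda_i}.
#'
#' @inheritParams linear_predictor
#' @return positive vector \eqn{\lambda}.
#' @export
relative_risk <- function(params, s, data) {
  exp(latent_shift(data, params, s))
}
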