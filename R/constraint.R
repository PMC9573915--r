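#' Sum-to-zero constraint specification
#'
#' The improper ICAR density is constant along each connected component's
#' indicator direction, so the latent field is identified only up to
#' per-component constants; the sum-to-zero constraint removes them.  Two
#' implementations are offered: `hard_reparameterize` writes
#' \eqn{s = A u} with \eqn{A} an orthonormal basis of the per-component
#' sum-to-zero subspace and optimizes/integrates over \eqn{u};
#' `soft_penalty` keeps all \eqn{n} coordinates and adds a Gaussian
#' penalty \eqn{\kappa/2 \, (\sum_{i \in c} s_i)^2} per component.
#'
#' @param mode `"hard_reparameterize"` (default) or `"soft_penalty"`.
#' @param soft_precision penalty precision \eqn{\kappa \ge 10^4} (soft
#'   mode only).
#' @return object of class `constraint_spec`.
#' @export
constraint_spec <- function(mode = c("hard_reparameterize", "soft_penalty"),
                            soft_precision = 1e6) {
  mode <- match.arg(mode)
  if (mode == "soft_penalty" && (!is.finite(soft_precision) || soft_precision < 1e4))
    stop("soft_precision must be >= 1e4")
  structure(list(mode = mode, soft_precision = soft_precision),
            class = "constraint_spec")
}

# Orthonormal basis of the per-component sum-to-zero subspace, built from
# normalized Helmert contrasts blockwise (deterministic, no QR pivoting).
# n x (n - k); components of size 1 contribute no columns (s_i fixed at 0).
sum_to_zero_basis <- function(graph) {
  cache <- graph$cache
  if (!is.null(cache$basis)) return(cache$basis)
  n <- graph$n_regions
  comps <- connected_components(graph)
  m <- n - length(comps)
  A <- matrix(0, n, m)
  col <- 0L
  for (idx in comps) {
    nc <- length(idx)
    if (nc < 2L) next
    Hm <- stats::contr.helmert(nc)
    Hm <- sweep(Hm, 2L, sqrt(colSums(Hm^2)), "/")
    A[idx, col + seq_len(nc - 1L)] <- Hm
    col <- col + nc - 1L
  }
  cache$basis <- A
  A
}

# A' Q A for the hard basis (constant per graph, cached)
basis_quadratic <- function(graph) {
  cache <- graph$cache
  if (is.null(cache$AQA)) {
    A <- sum_to_zero_basis(graph)
    cache$AQA <- crossprod(A, as.matrix(graph$Q) %*% A)
  }
  cache$AQA
}

graph_Q_dense <- function(graph) {
  cache <- graph$cache
  if (is.null(cache$Qd)) cache$Qd <- as.matrix(graph$Q)
  cache$Qd
}

# component indicator matrix, n x k (dense; k is small)
component_indicators <- function(graph) {
  cache <- graph$cache
  if (is.null(cache$compind)) {
    M <- matrix(0, graph$n_regions, graph$n_components)
    M[cbind(seq_len(graph$n_regions), graph$components)] <- 1
    cache$compind <- M
  }
  cache$compind
}
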