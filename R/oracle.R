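# Independent brute-force computations that adjudicate the Laplace
# machinery on tiny instances: dense eigendecomposition for the pseudo-
# determinant, tensor-product adaptive quadrature in the eigenbasis of Q
# for the marginal likelihood, and a complete-the-square closed form for
# the Gaussian-surrogate likelihood.

#' Log pseudo-determinant and rank of the ICAR structure matrix
#'
#' The structure matrix \eqn{Q = D_w - W} is singular (its covariance
#' inverse does not exist); the improper density is normalized through
#' the product of its positive eigenvalues instead.
#'
#' @param graph a [spatial_graph()] with at most 5000 regions.
#' @return list with `log_pdet` (sum of logs of the \eqn{n-k} positive
#'   eigenvalues) and `rank` (\eqn{n-k}).
#' @export
pseudo_determinant <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  list(log_pdet = graph_log_pdet(graph),
       rank = graph$n_regions - graph$n_components)
}

#' Brute-force marginal negative log-likelihood by quadrature
#'
#' Integrates \eqn{\exp(-\mathrm{nll}(\theta, s))} over the per-component
#' sum-to-zero subspace by nested adaptive quadrature in the eigenbasis
#' of \eqn{Q}, entirely independent of the Laplace code path.  Cost grows
#' exponentially in the constrained dimension, hence the hard cap.
#'
#' @param data a [model_data()].
#' @param params an [icar_params()].
#' @param max_dim refuse when the constrained dimension \eqn{n-k}
#'   exceeds this (default and ceiling 4).
#' @param rel_tol relative tolerance handed to [stats::integrate()]
#'   (quadrature method).
#' @param family `"poisson"` or `"gaussian_surrogate"`.
#' @param method `"adaptive_quadrature"`, `"importance_sampling"`, or
#'   `"auto"` (default): quadrature up to dimension 2, importance
#'   sampling above (nested adaptive quadrature in pure R is impractical
#'   past 2 dimensions; the sampler uses its own Nelder-Mead pilot mode
#'   and a heavy-tailed multivariate-t proposal, sharing nothing with the
#'   Laplace code path).
#' @param n_samples importance-sampling draws.
#' @param seed seed for the importance sampler.
#' @return scalar: \eqn{-\log} of the integral, with attributes
#'   `"error_estimate"` (outermost quadrature error or Monte-Carlo
#'   standard error, propagated to the log scale) and `"oracle_method"`.
#' @export
brute_force_marginal <- function(data, params, max_dim = 4L,
                                 rel_tol = 1e-8, family = "poisson",
                                 method = c("auto", "adaptive_quadrature",
                                            "importance_sampling"),
                                 n_samples = 6e5, seed = 101L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "model_data"))
  if (max_dim > 4L) stop("max_dim must be <= 4")
  graph <- data$graph
  m <- graph$n_regions - graph$n_components
  if (m > max_dim)
    stop(sprintf("constrained dimension %d exceeds max_dim %d", m, max_dim))
  lk <- likelihood_terms(data, params, family)
  fixed <- drop(params$beta0 +
                  if (ncol(data$X) > 0L) data$X %*% params$beta else 0)
  fixed <- rep_len(fixed, graph$n_regions)
  tau2 <- exp(2 * params$log_tau)
  eig <- graph_eigen(graph)
  vals <- eig$values[seq_len(m)]
  V <- eig$vectors[, seq_len(m), drop = FALSE]
  normc <- icar_log_normconst(graph, params$log_tau)
  # scale factor so the integrand is O(1) near its peak; a constant shift
  # on the log scale, removed at the end (independent of the Laplace fit)
  shift <- -lk$value(fixed) + normc
  if (m == 0L) return(structure(-shift + 0, error_estimate = 0))
  y <- data$y; E <- data$E; logE <- log(E)
  # columnwise likelihood value over a matrix of nu vectors
  value_mat <- if (family == "poisson") {
    function(nu) -(colSums(y * (logE + nu)) - colSums(E * exp(nu)))
  } else {
    mu0 <- E * exp(fixed)
    g0 <- mu0 - y
    v0 <- -sum(y * (logE + fixed) - mu0)
    function(nu) {
      d <- nu - fixed
      v0 + colSums(g0 * d) + 0.5 * colSums(mu0 * d^2)
    }
  }
  # negative log integrand over a matrix of u columns (m x N)
  neg_log_integrand <- function(U) {
    nu <- V %*% U + fixed
    value_mat(nu) + colSums(vals * U^2) / (2 * tau2) - normc
  }
  if (method == "auto")
    method <- if (m <= 2L) "adaptive_quadrature" else "importance_sampling"

  if (method == "adaptive_quadrature") {
    # vectorized innermost level: evaluate the integrand on a whole node
    # vector at once (n x length(t) matrix of linear predictors)
    dens_vec <- function(u_head, t) {
      s_base <- fixed +
        if (m > 1L) drop(V[, -m, drop = FALSE] %*% u_head) else 0
      nu <- outer(V[, m], t) + s_base
      lik <- value_mat(nu)
      quad <- (sum(vals[-m] * u_head^2) + vals[m] * t^2) / (2 * tau2)
      exp(-(lik + quad - normc) - shift)
    }
    err_outer <- NA_real_
    integ <- function(d, u_head) {
      # width of the prior in this eigendirection bounds the useful range
      sd_d <- sqrt(tau2 / vals[d]) + 1
      f <- if (d == m)
        function(t) dens_vec(u_head, t)
      else
        function(t) vapply(t, function(ti) integ(d + 1L, c(u_head, ti)),
                           numeric(1))
      res <- stats::integrate(f, lower = -12 * sd_d, upper = 12 * sd_d,
                              rel.tol = rel_tol, subdivisions = 200L)
      if (d == 1L) err_outer <<- res$abs.error
      res$value
    }
    I <- integ(1L, numeric(0))
    return(structure(-(log(I) + shift), error_estimate = err_outer / I,
                     oracle_method = "adaptive_quadrature"))
  }

  # importance sampling: pilot mode by Nelder-Mead (independent of the
  # package's Newton machinery), FD curvature for the proposal scale,
  # multivariate-t proposal with 7 df for tail safety
  f1 <- function(u) neg_log_integrand(matrix(u, ncol = 1L))
  pilot <- stats::optim(numeric(m), f1, method = "Nelder-Mead",
                        control = list(maxit = 5000L, reltol = 1e-12))
  ctr <- pilot$par
  h <- 1e-4
  curv <- vapply(seq_len(m), function(d) {
    e <- numeric(m); e[d] <- h
    (f1(ctr + e) - 2 * pilot$value + f1(ctr - e)) / h^2
  }, numeric(1))
  curv <- pmax(curv, 1e-8)
  scale <- 1.3 / sqrt(curv)
  df <- 7
  set.seed(as.integer(seed))
  # coordinates drawn as independent scaled t variates so the proposal
  # density is the exact product of univariate t densities
  Tm <- matrix(stats::rt(m * n_samples, df), m, n_samples)
  U <- ctr + scale * Tm
  logq <- colSums(stats::dt(Tm, df, log = TRUE)) - sum(log(scale))
  logw <- -(neg_log_integrand(U)) - logq
  mx <- max(logw)
  w <- exp(logw - mx)
  I_scaled <- mean(w)
  se_log <- stats::sd(w) / (sqrt(n_samples) * I_scaled)
  structure(-(log(I_scaled) + mx), error_estimate = se_log,
            oracle_method = "importance_sampling")
}

# closed-form Gaussian evidence for the surrogate likelihood, by
# completing the square in the eigenbasis of Q (independent of the inner
# Newton path)
gaussian_evidence <- function(data, params, constraint = constraint_spec()) {
  graph <- data$graph
  m <- graph$n_regions - graph$n_components
  nu0 <- drop(params$beta0 +
                if (ncol(data$X) > 0L) data$X %*% params$beta else 0)
  nu0 <- rep_len(nu0, graph$n_regions)
  mu0 <- data$E * exp(nu0)
  v0 <- -sum(data$y * (log(data$E) + nu0) - mu0)
  g0 <- mu0 - data$y
  tau2 <- exp(2 * params$log_tau)
  eig <- graph_eigen(graph)
  V <- eig$vectors[, seq_len(m), drop = FALSE]
  H <- crossprod(V, V * mu0) + diag(eig$values[seq_len(m)] / tau2, m)
  b <- -drop(crossprod(V, g0))
  normc <- icar_log_normconst(graph, params$log_tau)
  ch <- chol(H)
  w <- backsolve(ch, b, transpose = TRUE)
  (v0 - normc) - 0.5 * sum(w^2) + sum(log(diag(ch))) - (m / 2) * log(2 * pi)
}

#' Built-in oracle fixture set
#'
#' Small graphs (constrained dimension at most 3) with fixed counts and a
#' grid of parameter values, used to adjudicate the Laplace approximation
#' against brute-force quadrature.  Versioned: changing it invalidates
#' recorded comparisons.
#'
#' @return list of fixtures, each with `name`, `data` ([model_data()]),
#'   and `theta_grid` (list of [icar_params()]).
#' @export
oracle_fixtures <- function() {
  grid <- function(beta0s, log_taus)
    do.call(c, lapply(beta0s, function(b)
      lapply(log_taus, function(lt) icar_params(beta0 = b, log_tau = lt))))
  fixtures <- list(
    list(name = "single_edge_n2",
         graph = spatial_graph(rbind(c(1L, 2L)), 2L),
         y = c(0, 2), E = c(1, 1)),
    list(name = "path_n3",
         graph = spatial_graph(rbind(c(1L, 2L), c(2L, 3L)), 3L),
         y = c(3, 1, 0), E = c(1, 1, 1)),
    list(name = "cycle_n4",
         graph = spatial_graph(rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)), 4L),
         y = c(2, 0, 1, 4), E = c(1.5, 1, 0.5, 2)),
    list(name = "two_components_n5",
         # path on 1-2-3 plus disjoint edge 4-5: exercises the k = 2
         # normalization while keeping the constrained dimension at 3
         graph = spatial_graph(rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)), 5L),
         y = c(5, 1, 0, 2, 1), E = c(2, 1, 1, 1, 1)))
  lapply(fixtures, function(fx) {
    list(name = fx$name,
         data = model_data(fx$y, fx$E, fx$graph),
         theta_grid = grid(c(-0.5, 0, 0.5), c(-0.7, 0, 0.7)))
  })
}

#' Run the oracle validation suite
#'
#' For each fixture and parameter-grid point, computes the Laplace
#' marginal nll and the brute-force quadrature value and reports the
#' absolute discrepancy alongside the oracle's own error estimate.
#'
#' @param fixtures fixture list (default [oracle_fixtures()]).
#' @param constraint a [constraint_spec()].
#' @param rel_tol quadrature tolerance.
#' @return data.frame of class `oracle_report` (one row per instance):
#'   `instance`, `beta0`, `log_tau`, `laplace_value`, `oracle_value`,
#'   `abs_error`, `oracle_method`, `oracle_error_estimate`.
#' @export
run_oracle_validation <- function(fixtures = oracle_fixtures(),
                                  constraint = constraint_spec(),
                                  rel_tol = 1e-8) {
  rows <- list()
  for (fx in fixtures) {
    for (th in fx$theta_grid) {
      lap <- as.numeric(marginal_nll(fx$data, th, constraint))
      orc <- brute_force_marginal(fx$data, th, max_dim = 4L,
                                  rel_tol = rel_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        instance = fx$name, beta0 = th$beta0, log_tau = th$log_tau,
        laplace_value = lap, oracle_value = as.numeric(orc),
        abs_error = abs(lap - as.numeric(orc)),
        oracle_method = attr(orc, "oracle_method"),
        oracle_error_estimate = attr(orc, "error_estimate"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("oracle_report", class(out))
  out
}
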