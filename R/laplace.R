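# Laplace-approximated marginal likelihood for the Poisson-ICAR model:
# the latent field is profiled out by an inner Newton solve (the joint nll
# is strictly convex in s for fixed theta), and the marginal nll over
# theta is minimized by quasi-Newton with finite-difference gradients.

# Data-likelihood term as a function of nu = beta0 + X beta + s.
# family "poisson" is the model; "gaussian_surrogate" replaces the Poisson
# term by its second-order expansion around nu0 = beta0 + X beta (s = 0),
# for which the Laplace approximation is exact.
likelihood_terms <- function(data, params, family = c("poisson", "gaussian_surrogate")) {
  family <- match.arg(family)
  y <- data$y; E <- data$E; logE <- log(E)
  if (family == "poisson") {
    list(
      value = function(nu) {
        mu <- E * exp(nu)
        if (any(!is.finite(mu))) {
          bad <- which(!is.finite(mu))[1L]
          stop(sprintf("overflow in exp(eta) at region index %d", bad))
        }
        -sum(y * (logE + nu) - mu)
      },
      grad = function(nu) E * exp(nu) - y,
      curv = function(nu) E * exp(nu))
  } else {
    nu0 <- drop(params$beta0 +
                  if (ncol(data$X) > 0L) data$X %*% params$beta else 0)
    nu0 <- rep_len(nu0, length(y))
    mu0 <- E * exp(nu0)
    v0 <- -sum(y * (logE + nu0) - mu0)
    g0 <- mu0 - y
    list(
      value = function(nu) {
        d <- nu - nu0
        v0 + sum(g0 * d) + 0.5 * sum(mu0 * d^2)
      },
      grad = function(nu) g0 + mu0 * (nu - nu0),
      curv = function(nu) mu0)
  }
}

#' Inner Newton solve for the latent-field mode
#'
#' Minimizes the joint negative log-likelihood over the latent field for
#' fixed parameters, on the constrained subspace (hard mode) or with the
#' soft quadratic penalty.  The Hessian
#' \eqn{H(s) = \mathrm{diag}(E_i e^{\eta_i}) + Q/\tau^2} (plus penalty) is
#' positive definite on the working space, so undamped Newton with
#' step-halving converges monotonically.
#'
#' @param data a [model_data()].
#' @param params an [icar_params()].
#' @param constraint a [constraint_spec()].
#' @param start optional starting latent field (length `n_regions`).
#' @param tol sup-norm gradient tolerance (inner; default `1e-8`).
#' @param max_iter Newton iteration cap (convergence failure past it).
#' @param family internal hook for the Gaussian-surrogate exactness checks.
#' @return list with `s` (latent field), `u` (working coordinates), `f`
#'   (joint nll at the mode, without the ICAR normalizing constant),
#'   `chol_H` (upper Cholesky factor of the inner Hessian), `iterations`,
#'   `max_grad`.
#' @export
inner_mode <- function(data, params, constraint = constraint_spec(),
                       start = NULL, tol = 1e-8, max_iter = 200L,
                       family = "poisson") {
  stopifnot(inherits(data, "model_data"), inherits(constraint, "constraint_spec"))
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  graph <- data$graph
  n <- graph$n_regions
  lk <- likelihood_terms(data, params, family)
  tau2 <- exp(2 * params$log_tau)
  fixed <- drop(params$beta0 +
                  if (ncol(data$X) > 0L) data$X %*% params$beta else 0)
  fixed <- rep_len(fixed, n)
  hard <- constraint$mode == "hard_reparameterize"

  if (hard) {
    A <- sum_to_zero_basis(graph)
    P <- basis_quadratic(graph) / tau2          # prior precision in u
    to_s <- function(u) if (ncol(A)) drop(A %*% u) else numeric(n)
    u <- if (is.null(start)) numeric(ncol(A)) else drop(crossprod(A, start))
    if (!all(is.finite(u))) stop("start must be finite")
    fn <- function(u) {
      su <- to_s(u)
      lk$value(fixed + su) + 0.5 * sum(u * (P %*% u))
    }
    gr_hess <- function(u) {
      su <- to_s(u)
      gnu <- lk$grad(fixed + su)
      w <- lk$curv(fixed + su)
      list(g = drop(crossprod(A, gnu)) + drop(P %*% u),
           H = crossprod(A, A * w) + P)
    }
  } else {
    kappa <- constraint$soft_precision
    M <- component_indicators(graph)
    Qd <- graph_Q_dense(graph)
    u <- if (is.null(start)) numeric(n) else as.numeric(start)
    if (!all(is.finite(u))) stop("start must be finite")
    fn <- function(s) {
      cs <- drop(crossprod(M, s))
      lk$value(fixed + s) + sum(s * (Qd %*% s)) / (2 * tau2) +
        0.5 * kappa * sum(cs^2)
    }
    gr_hess <- function(s) {
      gnu <- lk$grad(fixed + s)
      w <- lk$curv(fixed + s)
      cs <- drop(crossprod(M, s))
      list(g = gnu + drop(Qd %*% s) / tau2 + kappa * drop(M %*% cs),
           H = Qd / tau2 + kappa * tcrossprod(M) + diag(w, length(s)))
    }
  }

  f <- fn(u)
  iter <- 0L
  R <- NULL
  max_grad <- Inf
  if (length(u) == 0L) {
    # fully disconnected graph: latent field identically 0
    return(list(s = numeric(n), u = u, f = f,
                chol_H = matrix(numeric(0), 0L, 0L),
                iterations = 0L, max_grad = 0))
  }
  repeat {
    gh <- gr_hess(u)
    max_grad <- max(abs(gh$g))
    R <- chol(gh$H)
    if (max_grad <= tol) break
    if (iter >= max_iter)
      stop(sprintf("inner Newton failed to converge in %d iterations (max gradient %.3e)",
                   max_iter, max_grad))
    iter <- iter + 1L
    step <- backsolve(R, backsolve(R, gh$g, transpose = TRUE))
    alpha <- 1
    repeat {
      u_new <- u - alpha * step
      f_new <- tryCatch(fn(u_new), error = function(e) Inf)
      if (is.finite(f_new) && f_new <= f + 1e-12 * (1 + abs(f))) break
      alpha <- alpha / 2
      if (alpha < 1e-12)
        stop("inner Newton step-halving failed to find a decreasing step")
    }
    u <- u_new
    f <- f_new
  }
  s <- if (hard) to_s(u) else u
  list(s = s, u = u, f = f, chol_H = R, iterations = iter, max_grad = max_grad)
}

# tau-dependent normalizing constant of the soft-penalized (proper) prior
soft_log_normconst <- function(graph, log_tau, kappa) {
  n <- graph$n_regions
  comps <- connected_components(graph)
  r <- n - length(comps)
  -(n / 2) * log(2 * pi) + 0.5 * graph_log_pdet(graph) - r * log_tau +
    0.5 * sum(log(kappa * lengths(comps)))
}

#' Laplace-approximated negative log marginal likelihood
#'
#' Approximates \eqn{-\log \int \exp(-\mathrm{nll}(\theta, s))\, ds}
#' (the integral running over the sum-to-zero subspace, or over all of
#' \eqn{R^n} with the soft penalty folded into a proper prior) by
#' \deqn{\mathrm{nll}^*(\theta) = \mathrm{nll}(\theta, \hat s) +
#'   \tfrac12 \log\det H(\hat s) - \tfrac m2 \log 2\pi,}
#' with \eqn{\hat s} the inner mode, \eqn{H} the inner Hessian and
#' \eqn{m} the integrated dimension (\eqn{n-k} hard, \eqn{n} soft).
#'
#' @inheritParams inner_mode
#' @return scalar `nll*`, with attribute `"inner"` carrying the inner
#'   solve (mode, Cholesky factor, iteration count).
#' @export
marginal_nll <- function(data, params, constraint = constraint_spec(),
                         start = NULL, inner_tol = 1e-8, family = "poisson") {
  inner <- inner_mode(data, params, constraint, start = start,
                      tol = inner_tol, family = family)
  m <- length(inner$u)
  logdetH <- if (m > 0L) 2 * sum(log(diag(inner$chol_H))) else 0
  normc <- if (constraint$mode == "hard_reparameterize")
    icar_log_normconst(data$graph, params$log_tau)
  else
    soft_log_normconst(data$graph, params$log_tau, constraint$soft_precision)
  val <- (inner$f - normc) + 0.5 * logdetH - (m / 2) * log(2 * pi)
  attr(val, "inner") <- inner
  val
}

# central finite-difference gradient with relative step
fd_gradient <- function(fn, theta, step = 1e-5) {
  vapply(seq_along(theta), function(j) {
    h <- step * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(fn, theta, step = 1e-4) {
  p <- length(theta)
  h <- step * (1 + abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- fn(theta)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    H[j, j] <- (fn(tp) - 2 * f0 + fn(tm)) / h[j]^2
    if (j < p) for (l in seq((j + 1L), p)) {
      tpp <- theta; tpp[c(j, l)] <- tpp[c(j, l)] + h[c(j, l)]
      tpm <- theta; tpm[j] <- tpm[j] + h[j]; tpm[l] <- tpm[l] - h[l]
      tmp <- theta; tmp[j] <- tmp[j] - h[j]; tmp[l] <- tmp[l] + h[l]
      tmm <- theta; tmm[c(j, l)] <- tmm[c(j, l)] - h[c(j, l)]
      H[j, l] <- H[l, j] <-
        (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * h[j] * h[l])
    }
  }
  H
}

#' Maximum likelihood fit of the Poisson-ICAR model
#'
#' Minimizes the Laplace-approximated marginal negative log-likelihood
#' over \eqn{\theta = (\beta_0, \beta, \log\tau)} by BFGS with central
#' finite-difference gradients, warm-starting the inner Newton solve
#' across evaluations.  Standard errors come from the inverse
#' finite-difference Hessian of \eqn{\mathrm{nll}^*} at the optimum and
#' are delta-method-transformed to the reporting scale.
#'
#' @param data a [model_data()].
#' @param constraint a [constraint_spec()].
#' @param init optional [icar_params()] starting value; default is the
#'   moment-matched intercept \eqn{\log(\sum y / \sum E)}, zero
#'   coefficients, \eqn{\log\tau = 0}.
#' @param outer_tol sup-norm tolerance for the outer gradient (default
#'   `1e-4`; a fit is `converged` only if met).
#' @param report_scale `"tau2"` (default; the variance-scale quantity
#'   \eqn{\tau^2 = \sigma_s^2} reported as "spatial dispersion") or
#'   `"tau"`.
#' @param seed optional integer; recorded in the fit (the fit itself is
#'   deterministic given the data).
#' @param family internal hook for Gaussian-surrogate checks.
#' @param inner_tol inner Newton gradient tolerance.
#' @param max_outer outer iteration cap passed to [stats::optim()].
#' @return object of class `icar_fit`: parameter estimates and standard
#'   errors (`estimates`), plug-in latent field `s_hat` with conditional
#'   standard deviations `s_sd`, `marginal_nll`, `max_gradient`,
#'   `converged`, `boundary` (dispersion driven to ~0), iteration
#'   counters, and the inputs needed to reproduce the fit.
#' @examples
#' g <- lattice_graph(4, 4)
#' sim <- simulate_counts(sim_config(lattice_shape = g, true_beta0 = 0.2,
#'                                   true_tau_scale = 0.4, offsets = 20,
#'                                   seed = 7))
#' fit <- fit_mle(sim)
#' fit$estimates
#' @export
fit_mle <- function(data, constraint = constraint_spec(), init = NULL,
                    outer_tol = 1e-4, report_scale = c("tau2", "tau"),
                    seed = NULL, family = "poisson", inner_tol = 1e-8,
                    max_outer = 500L) {
  stopifnot(inherits(data, "model_data"))
  report_scale <- match.arg(report_scale)
  p <- ncol(data$X)
  if (is.null(init))
    init <- icar_params(beta0 = log(sum(data$y) / sum(data$E)),
                        beta = rep(0, p), log_tau = 0)
  if (length(init$beta) != p) stop("init has the wrong number of coefficients")
  theta0 <- params_to_vec(init)

  state <- new.env(parent = emptyenv())
  state$warm <- NULL
  state$trace <- integer(0)
  obj <- function(theta) {
    val <- tryCatch(
      marginal_nll(data, vec_to_params(theta, p), constraint,
                   start = state$warm, inner_tol = inner_tol,
                   family = family),
      error = function(e) structure(1e10, inner = NULL))
    inner <- attr(val, "inner")
    if (!is.null(inner)) {
      state$warm <- inner$s
      state$trace <- c(state$trace, inner$iterations)
    }
    as.numeric(val)
  }
  grad <- function(theta) fd_gradient(obj, theta)

  opt <- stats::optim(theta0, obj, grad, method = "BFGS",
                      control = list(maxit = max_outer, reltol = 1e-12))
  # Newton polish on theta: BFGS's relative-decrease stop can fire while
  # the gradient is still above the tolerance when |nll*| is large
  theta_hat <- opt$par
  fbest <- opt$value
  g <- grad(theta_hat)
  polish <- 0L
  while (max(abs(g)) > 0.5 * outer_tol && polish < 10L) {
    Hp <- fd_hessian(obj, theta_hat)
    step <- tryCatch(solve(Hp, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    alpha <- 1
    improved <- FALSE
    while (alpha > 1e-4) {
      cand <- theta_hat - alpha * step
      fc <- obj(cand)
      g_cand <- grad(cand)
      if (fc <= fbest + 1e-9 * (1 + abs(fbest)) &&
          max(abs(g_cand)) < max(abs(g))) {
        theta_hat <- cand; fbest <- fc; g <- g_cand; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    polish <- polish + 1L
  }
  opt$par <- theta_hat
  opt$value <- fbest
  params_hat <- vec_to_params(theta_hat, p)
  max_gradient <- max(abs(g))
  converged <- (opt$convergence == 0L) && (max_gradient <= outer_tol)
  tau2_hat <- exp(2 * params_hat$log_tau)
  boundary <- tau2_hat < 1e-3

  H <- fd_hessian(obj, theta_hat)
  se <- rep(NA_real_, length(theta_hat))
  vcov <- NULL
  ev <- try(eigen(H, symmetric = TRUE, only.values = TRUE)$values, silent = TRUE)
  if (!inherits(ev, "try-error") && all(ev > 0)) {
    vcov <- solve(H)
    se <- sqrt(diag(vcov))
  } else {
    warning("observed information is not positive definite; standard errors reported as missing")
  }
  names(se) <- names(theta_hat)

  # plug-in latent field and conditional SDs at the optimum
  inner <- inner_mode(data, params_hat, constraint, start = state$warm,
                      tol = inner_tol, family = family)
  s_sd <- rep(0, data$graph$n_regions)
  if (length(inner$u) > 0L) {
    R <- inner$chol_H
    if (constraint$mode == "hard_reparameterize") {
      A <- sum_to_zero_basis(data$graph)
      B <- t(backsolve(R, t(A), transpose = TRUE))  # A R^{-1}
      s_sd <- sqrt(rowSums(B^2))
    } else {
      s_sd <- sqrt(diag(chol2inv(R)))
    }
  }

  # reporting-scale transform for the dispersion (delta method)
  lt <- params_hat$log_tau
  se_lt <- se[["log_tau"]]
  disp <- if (report_scale == "tau2")
    c(exp(2 * lt), 2 * exp(2 * lt) * se_lt)
  else
    c(exp(lt), exp(lt) * se_lt)
  terms <- c("intercept",
             if (p > 0L) {
               cn <- colnames(data$X)
               if (is.null(cn)) paste0("beta", seq_len(p)) else cn
             },
             sprintf("spatial_dispersion_%s", report_scale))
  estimates <- data.frame(
    term = terms,
    estimate = c(theta_hat[seq_len(1L + p)], disp[1L]),
    se = c(se[seq_len(1L + p)], disp[2L]),
    stringsAsFactors = FALSE)

  fit <- structure(list(
    theta_hat = params_hat,
    theta_vec = theta_hat,
    se_theta = se,
    vcov = vcov,
    estimates = estimates,
    s_hat = inner$s,
    s_sd = s_sd,
    marginal_nll = opt$value,
    max_gradient = max_gradient,
    outer_tol = outer_tol,
    converged = converged,
    boundary = boundary,
    n_outer_iterations = unname(opt$counts[1L]),
    inner_newton_trace = state$trace,
    constraint = constraint,
    report_scale = report_scale,
    family = family,
    seed = seed,
    init = theta0,
    optimizer = list(method = "BFGS", reltol = 1e-12,
                     gradient = "central finite differences",
                     fd_step = 1e-5),
    data = data), class = "icar_fit")
  if (boundary)
    warning("spatial dispersion estimate is at the zero boundary (no spatial signal)")
  fit
}

#' @export
print.icar_fit <- function(x, ...) {
  cat("Poisson-ICAR model fit (Laplace-approximated maximum likelihood)\n")
  est <- x$estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-26s %8.3f (%.3f)\n", est$term[i], est$estimate[i], est$se[i]))
  cat(sprintf("  marginal nll: %.4f   max |gradient|: %.2e (tol %.0e)\n",
              x$marginal_nll, x$max_gradient, x$outer_tol))
  cat(sprintf("  converged: %s%s   outer iterations: %d\n",
              x$converged, if (x$boundary) " [dispersion at zero boundary]" else "",
              x$n_outer_iterations))
  invisible(x)
}

#' Plug-in estimate of the latent spatial field
#'
#' Returns the latent field at its conditional mode given the MLEs (the
#' empirical-Bayes plug-in estimate) with conditional standard deviations
#' from the diagonal of the inverse inner Hessian.
#'
#' @param fit a converged [fit_mle()] result.
#' @return data.frame with `region_label`, `s_hat`, `cond_sd`.
#' @export
plug_in_latent <- function(fit) {
  stopifnot(inherits(fit, "icar_fit"))
  if (!fit$converged)
    stop("fit did not converge; refusing to report plug-in latent estimates")
  data.frame(region_label = fit$data$graph$region_labels,
             s_hat = fit$s_hat,
             cond_sd = fit$s_sd,
             stringsAsFactors = FALSE)
}
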