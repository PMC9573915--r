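test_that("inner_mode returns s = 0 on null data and under extreme shrinkage", {
  g <- cycle_graph(6)
  # y = E exp(beta0) exactly (E chosen as y / exp(beta0)): the joint
  # gradient vanishes at s = 0
  b0 <- 0.4
  y <- c(3, 6, 2, 4, 3, 3)
  d <- model_data(y, y / exp(b0), g)
  m <- inner_mode(d, icar_params(b0, log_tau = 0.2))
  expect_equal(m$s, rep(0, 6), tolerance = 1e-8)
  # tau -> 0: infinite shrinkage regardless of the data
  d2 <- model_data(c(9, 0, 1, 4, 0, 2), rep(1, 6), g)
  m2 <- inner_mode(d2, icar_params(0, log_tau = -8))
  expect_lt(max(abs(m2$s)), 1e-4)
})

test_that("inner_mode matches a dense general-purpose optimizer", {
  g <- path_graph(3)
  d <- model_data(c(3, 1, 0), rep(1, 3), g)
  th <- icar_params(0, log_tau = 0)
  m <- inner_mode(d, th)
  # oracle: optim over the 2-d coefficient space of an independent basis
  V <- eigen(as.matrix(g$Q), symmetric = TRUE)$vectors[, 1:2]
  f <- function(u) {
    s <- drop(V %*% u)
    -sum(d$y * s - exp(s)) + icar_quadratic(s, g) / 2
  }
  o <- optim(c(0, 0), f, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(m$s, drop(V %*% o$par), tolerance = 1e-6)
  expect_lte(m$max_grad, 1e-8)
  # component sums vanish
  expect_equal(sum(m$s), 0, tolerance = 1e-12)
})

test_that("Newton iterates decrease the joint nll monotonically from s = 0", {
  set.seed(2)
  sim <- simulate_counts(sim_config(lattice_shape = c(4, 5), offsets = 10,
                                    true_tau_scale = 0.8, seed = 13))
  th <- icar_params(0.5, log_tau = log(0.8))
  # re-run Newton manually, tracking the objective
  A <- icarlap:::sum_to_zero_basis(sim$graph)
  P <- icarlap:::basis_quadratic(sim$graph) / 0.8^2
  u <- numeric(ncol(A))
  fn <- function(u) {
    s <- drop(A %*% u)
    nu <- 0.5 + s
    -sum(sim$y * (log(sim$E) + nu) - sim$E * exp(nu)) + 0.5 * sum(u * (P %*% u))
  }
  fvals <- fn(u)
  for (it in 1:50) {
    s <- drop(A %*% u)
    mu <- sim$E * exp(0.5 + s)
    gkt <- drop(crossprod(A, mu - sim$y)) + drop(P %*% u)
    if (max(abs(gkt)) < 1e-10) break
    H <- crossprod(A, A * mu) + P
    u <- u - solve(H, gkt)
    fvals <- c(fvals, fn(u))
  }
  expect_true(all(diff(fvals) <= 1e-10))
  # and the packaged solver lands at the same optimum
  m <- inner_mode(sim, th)
  expect_equal(m$f, fvals[length(fvals)], tolerance = 1e-9)
})

test_that("marginal_nll matches quadrature on tiny graphs", {
  g <- spatial_graph(rbind(c(1L, 2L)), 2L)
  d <- model_data(c(0, 0), c(1, 1), g)
  th <- icar_params(0, log_tau = 0)
  lap <- as.numeric(marginal_nll(d, th))
  orc <- as.numeric(brute_force_marginal(d, th))
  expect_lt(abs(lap - orc), 0.05)
  # 4-region path, small counts
  g4 <- path_graph(4)
  d4 <- model_data(c(1, 0, 2, 1), rep(1, 4), g4)
  lap4 <- as.numeric(marginal_nll(d4, th))
  orc4 <- as.numeric(brute_force_marginal(d4, th, method = "importance_sampling"))
  expect_lt(abs(lap4 - orc4), 0.05)
})

test_that("Laplace is exact for the Gaussian-surrogate likelihood", {
  set.seed(8)
  for (gr in list(path_graph(4), cycle_graph(5),
                  spatial_graph(rbind(c(1L, 2L), c(3L, 4L)), 4L))) {
    y <- rpois(gr$n_regions, 2)
    E <- runif(gr$n_regions, 0.5, 2)
    d <- model_data(y, E, gr)
    th <- icar_params(0.2, log_tau = -0.1)
    lap <- as.numeric(marginal_nll(d, th, family = "gaussian_surrogate"))
    closed <- icarlap:::gaussian_evidence(d, th)
    expect_equal(lap, closed, tolerance = 1e-10)
  }
})

test_that("hard and soft constraint fits agree", {
  sim <- simulate_counts(sim_config(lattice_shape = c(4, 4), offsets = 25,
                                    seed = 31))
  th <- icar_params(0.4, log_tau = -0.3)
  hard <- as.numeric(marginal_nll(sim, th, constraint_spec()))
  soft <- as.numeric(marginal_nll(sim, th,
                                  constraint_spec("soft_penalty", 1e6)))
  expect_equal(hard, soft, tolerance = 1e-4)
  fit_h <- fit_mle(sim)
  fit_s <- fit_mle(sim, constraint_spec("soft_penalty", 1e6))
  expect_equal(fit_h$theta_vec, fit_s$theta_vec, tolerance = 5e-4)
  expect_error(constraint_spec("soft_penalty", 10), ">= 1e4")
})

test_that("fit_mle recovers parameters and satisfies its own contracts", {
  sim <- simulate_counts(sim_config(lattice_shape = c(8, 8), offsets = 50,
                                    seed = 17))
  fit <- fit_mle(sim)
  expect_true(fit$converged)
  expect_lte(fit$max_gradient, 1e-4)
  expect_false(fit$boundary)
  expect_lt(abs(fit$theta_hat$beta0 - 0.5), 0.15)
  expect_true(all(fit$estimates$se > 0))
  # dispersion reporting scales are consistent (delta method)
  fit_tau <- fit_mle(sim, report_scale = "tau")
  est2 <- fit$estimates$estimate[2]
  expect_equal(fit_tau$estimates$estimate[2]^2, est2, tolerance = 1e-8)
  expect_equal(fit$estimates$se[2],
               2 * fit_tau$estimates$estimate[2] * fit_tau$estimates$se[2],
               tolerance = 1e-8)
})

test_that("no spatial signal drives the dispersion to the boundary with a flag", {
  # s = 0 and large E: the profile likelihood pushes tau to 0
  g <- lattice_graph(5, 5)
  set.seed(4)
  E <- rep(500, 25)
  y <- rpois(25, E * exp(0.2))
  d <- model_data(y, E, g)
  ws <- capture_warnings(fit <- fit_mle(d))
  expect_true(any(grepl("boundary", ws)))
  expect_true(fit$boundary)
  expect_lt(exp(2 * fit$theta_hat$log_tau), 1e-3)
})

test_that("plug_in_latent honours the convergence contract", {
  sim <- simulate_counts(sim_config(lattice_shape = c(4, 4), offsets = 30,
                                    seed = 23))
  fit <- fit_mle(sim)
  pl <- plug_in_latent(fit)
  expect_equal(sum(pl$s_hat), 0, tolerance = 1e-6)
  expect_true(all(pl$cond_sd > 0))
  # dense-oracle check of the conditional SDs on a 3-region path
  d3 <- model_data(c(3, 1, 0), rep(1, 3), path_graph(3))
  fit3 <- fit_mle(d3)
  th <- fit3$theta_hat
  m <- inner_mode(d3, th)
  A <- icarlap:::sum_to_zero_basis(d3$graph)
  mu <- d3$E * exp(th$beta0 + m$s)
  Hd <- crossprod(A, A * mu) +
    crossprod(A, as.matrix(d3$graph$Q) %*% A) / exp(2 * th$log_tau)
  ref_sd <- sqrt(diag(A %*% solve(Hd) %*% t(A)))
  expect_equal(fit3$s_sd, ref_sd, tolerance = 1e-6)
  # refusal on unconverged fits
  fake <- fit
  fake$converged <- FALSE
  expect_error(plug_in_latent(fake), "refus")
})

test_that("fits are deterministic for fixed data", {
  sim <- simulate_counts(sim_config(lattice_shape = c(4, 4), offsets = 20,
                                    seed = 37))
  f1 <- fit_mle(sim)
  f2 <- fit_mle(sim)
  expect_identical(f1$theta_vec, f2$theta_vec)
  expect_identical(f1$marginal_nll, f2$marginal_nll)
})
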