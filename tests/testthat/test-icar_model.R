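test_that("model_data validates shapes, counts and offsets", {
  g <- path_graph(3)
  expect_s3_class(model_data(c(0, 1, 2), c(1, 1, 1), g), "model_data")
  expect_error(model_data(c(0, 1), c(1, 1, 1), g), "length")
  expect_error(model_data(c(0, 1, 2), c(1, 0, 1), g), "positive")
  expect_error(model_data(c(0, 1.5, 2), c(1, 1, 1), g), "integer")
  expect_error(model_data(c(0, 1, 2), c(1, 1, 1), g, X = matrix(1, 2, 1)),
               "rows")
})

test_that("linear_predictor matches direct substitution", {
  g <- spatial_graph(rbind(c(1L, 2L)), 2L)
  d <- model_data(c(0, 0), c(1, 1), g)
  expect_equal(linear_predictor(d, icar_params(0), c(0, 0)), c(0, 0))
  d2 <- model_data(c(0, 0), c(2, 2), g)
  expect_equal(linear_predictor(d2, icar_params(0.5), c(0.1, -0.1)),
               c(log(2) + 0.6, log(2) + 0.4))
  # offset positivity enforced at construction
  expect_error(model_data(c(0, 0), c(2, -1), g), "positive")
})

test_that("icar_quadratic agrees with pairwise and dense-matrix forms", {
  g <- path_graph(3)
  expect_equal(icar_quadratic(c(5, 5, 5), g), 0)
  expect_equal(icar_quadratic(c(1, 0, -1), g), 2)
  set.seed(11)
  for (rep in 1:5) {
    gr <- random_graph(8)
    s <- rnorm(8)
    dense <- as.numeric(t(s) %*% (diag(rowSums(as.matrix(gr$W))) -
                                    as.matrix(gr$W)) %*% s)
    expect_equal(icar_quadratic(s, gr), dense, tolerance = 1e-12)
  }
})

test_that("icar_log_density: unnormalized form, tau-scaling identity", {
  g <- cycle_graph(5)
  expect_equal(icar_log_density(rep(0, 5), g, log_tau = 0.3,
                                normalized = FALSE), 0)
  s <- c(0.4, -0.2, 0.1, -0.5, 0.2)
  s <- s - mean(s)
  for (tau in c(0.5, 1.3)) {
    n_k <- 5 - 1
    q <- icar_quadratic(s, g)
    diff <- icar_log_density(s, g, log(2 * tau)) -
      icar_log_density(s, g, log(tau))
    expect_equal(diff, -n_k * log(2) + (q / 2) * (1 / tau^2 - 1 / (4 * tau^2)),
                 tolerance = 1e-12)
  }
  expect_error(icar_log_density(c(NA, 0, 0, 0, 0), g, 0), "finite")
})

test_that("normalized ICAR density equals the spectrally reduced Gaussian", {
  # on the sum-to-zero subspace, s = V u with V the positive eigenvectors
  # of Q; the density of u is N(0, tau^2 diag(1/lambda))
  g <- path_graph(3)
  eig <- eigen(as.matrix(g$Q), symmetric = TRUE)
  V <- eig$vectors[, 1:2]
  lam <- eig$values[1:2]
  s <- c(1, 0, -1)
  u <- drop(crossprod(V, s))
  for (lt in c(-0.4, 0, 0.6)) {
    tau <- exp(lt)
    ref <- sum(stats::dnorm(u, 0, tau / sqrt(lam), log = TRUE))
    expect_equal(icar_log_density(s, g, lt), ref, tolerance = 1e-10)
  }
})

test_that("normalized ICAR density integrates to 1 on the constrained subspace", {
  # Monte Carlo check on a tiny graph: draw u from a wide product
  # proposal, importance-weight the normalized density
  g <- spatial_graph(rbind(c(1L, 2L), c(2L, 3L)), 3L)
  eig <- eigen(as.matrix(g$Q), symmetric = TRUE)
  V <- eig$vectors[, 1:2]
  set.seed(3)
  N <- 5e4
  prop_sd <- 4
  U <- matrix(rnorm(2 * N, 0, prop_sd), 2L)
  logq <- colSums(dnorm(U, 0, prop_sd, log = TRUE))
  logp <- apply(U, 2L, function(u)
    icar_log_density(drop(V %*% u), g, log_tau = 0.2))
  int <- mean(exp(logp - logq))
  expect_lt(abs(int - 1), 3 * sd(exp(logp - logq)) / sqrt(N))
})

test_that("joint_nll matches hand values and a scalar Poisson oracle", {
  g <- path_graph(3)
  d <- model_data(c(0, 0, 0), c(1, 1, 1), g)
  expect_equal(joint_nll(d, icar_params(0), rep(0, 3), normalized = FALSE), 3)
  expect_equal(joint_nll(d, icar_params(log(2)), rep(0, 3),
                         normalized = FALSE), 6)
  # scalar-summation oracle on a 4-cycle with random data
  set.seed(21)
  gc <- cycle_graph(4)
  y <- rpois(4, 3)
  E <- runif(4, 0.5, 2)
  X <- matrix(rnorm(4), 4, 1)
  d2 <- model_data(y, E, gc, X)
  th <- icar_params(0.3, beta = 0.5, log_tau = -0.2)
  s <- rnorm(4); s <- s - mean(s)
  eta <- log(E) + 0.3 + 0.5 * X[, 1] + s
  oracle <- -sum(dpois(y, exp(eta), log = TRUE) + lfactorial(y)) +
    sum((s[c(1, 2, 3, 4)] - s[c(2, 3, 4, 1)])^2) / (2 * exp(-0.4))
  expect_equal(joint_nll(d2, th, s, normalized = FALSE), oracle,
               tolerance = 1e-10)
  expect_error(joint_nll(d2, icar_params(800, beta = 0, log_tau = 0), s),
               "overflow")
})

test_that("joint_nll is invariant under consistent relabeling", {
  set.seed(5)
  g <- random_graph(7)
  y <- rpois(7, 2); E <- runif(7, 0.5, 2); X <- matrix(rnorm(14), 7, 2)
  d <- model_data(y, E, g, X)
  th <- icar_params(0.1, beta = c(0.2, -0.3), log_tau = 0.1)
  s <- rnorm(7)
  perm <- sample(7)
  gp <- spatial_graph(cbind(match(g$edges[, 1], perm), match(g$edges[, 2], perm)),
                      7L)
  dp <- model_data(y[perm], E[perm], gp, X[perm, , drop = FALSE])
  expect_equal(joint_nll(dp, th, s[perm]), joint_nll(d, th, s),
               tolerance = 1e-10)
})

test_that("relative_risk and the intercept score equation", {
  g <- path_graph(3)
  d <- model_data(c(1, 2, 0), c(1, 1, 1), g)
  expect_equal(relative_risk(icar_params(0), rep(0, 3), d), rep(1, 3))
  expect_equal(relative_risk(icar_params(log(2)), rep(0, 3), d), rep(2, 3))
  # score equation: at the joint mode over (beta0, s) with tau fixed the
  # fitted total equals the observed total (found by alternating the
  # exact intercept update with the inner latent solve)
  sim <- simulate_counts(sim_config(lattice_shape = c(5, 5), offsets = 20,
                                    seed = 9))
  b0 <- log(sum(sim$y) / sum(sim$E))
  s <- NULL
  for (it in 1:60) {
    m <- inner_mode(sim, icar_params(b0, log_tau = -0.5), start = s)
    s <- m$s
    b0 <- log(sum(sim$y) / sum(sim$E * exp(s)))
  }
  lam <- relative_risk(icar_params(b0, log_tau = -0.5), s, sim)
  expect_equal(sum(sim$E * lam), sum(sim$y), tolerance = 1e-8)
})

test_that("model_data_from_csv joins by label and reports mismatches", {
  g <- path_graph(3, c("B", "A", "C"))
  df <- data.frame(region_label = c("A", "C", "B"), y = c(1, 2, 3),
                   E = c(1, 2, 3), x1 = c(0.1, 0.2, 0.3))
  d <- model_data_from_csv(df, g, covariates = "x1")
  expect_equal(d$y, c(3, 1, 2))  # reordered to graph order B, A, C
  expect_equal(d$X[, 1], c(0.3, 0.1, 0.2))
  df_bad <- df; df_bad$region_label[1] <- "Z"
  expect_error(model_data_from_csv(df_bad, g), "mismatch.*Z")
  expect_error(model_data_from_csv(df, g, y_col = "missing"), "missing")
})
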