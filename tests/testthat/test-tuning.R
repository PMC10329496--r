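make_fit <- function(X, U, selected = rep(TRUE, ncol(X)), nclust = 1L) {
  list(U = U, selected = selected, n_selected = sum(selected),
       n_clusters = nclust)
}

test_that("cluster BIC hits its closed-form anchor points", {
  set.seed(50)
  X <- matrix(rnorm(40), 10, 4)
  n <- 10; p <- 4
  # U = column means, one cluster: RSS/pi = n by construction
  Ubar <- matrix(colMeans(X), n, p, byrow = TRUE)
  expect_equal(bic_cluster(X, make_fit(X, Ubar, nclust = 1L)),
               n + 1 * log(n) * p)
  # U = X, n clusters: zero residual
  expect_equal(bic_cluster(X, make_fit(X, X, nclust = n)),
               0 + n * log(n) * p)
  # random fit against a direct-formula oracle on selected columns
  U <- X + matrix(rnorm(40, 0, 0.3), n, p)
  sel <- c(TRUE, TRUE, FALSE, TRUE)
  fit <- make_fit(X, U, selected = sel, nclust = 3L)
  Xa <- X[, sel]; Ua <- U[, sel]
  oracle <- sum((Xa - Ua)^2) /
    (sum(sweep(Xa, 2, colMeans(Xa))^2) / n) + 3 * log(n) * 3
  expect_equal(bic_cluster(X, fit), oracle)
  # no selected features: worst score
  expect_warning(
    val <- bic_cluster(X, make_fit(X, U, selected = rep(FALSE, 4))), "no features")
  expect_identical(val, Inf)
})

test_that("feature BIC hits its closed-form anchor points", {
  set.seed(51)
  X <- matrix(rnorm(60), 12, 5)
  n <- 12; p <- 5
  Ubar <- matrix(colMeans(X), n, p, byrow = TRUE)
  expect_equal(bic_feature(X, make_fit(X, Ubar, nclust = 1L)),
               n * p + 1 * p * log(n))
  expect_equal(bic_feature(X, make_fit(X, X, nclust = n)),
               0 + n * p * log(n))
  U <- X + matrix(rnorm(60, 0, 0.5), n, p)
  fit <- make_fit(X, U, nclust = 4L)
  oracle <- sum(vapply(1:p, function(j) {
    sum((X[, j] - U[, j])^2) / (sum((X[, j] - mean(X[, j]))^2) / n)
  }, 0)) + 4 * p * log(n)
  expect_equal(bic_feature(X, fit), oracle)
})

test_that("known targets equal to the data dimensions select zero penalties", {
  inst <- tiny_instance(60, n = 6, p = 4)
  tr <- tune_iscc(inst$X, inst$E, inst$z,
                  gamma1_grid = c(0, 0.5, 2), gamma2_grid = c(0, 0.5, 2),
                  mode = "known", K = 6, p_target = 4, refine_steps = 0L)
  expect_identical(c(tr$gamma1, tr$gamma2), c(0, 0))
  expect_identical(tr$fit$n_clusters, 6L)
  expect_identical(tr$fit$n_selected, 4L)
  # a stable pair confirms in the second round
  expect_identical(tr$rounds, 2L)
  expect_true(any(tr$path$gamma1 == 0 & tr$path$gamma2 == 0))
})

test_that("tuning is deterministic and its path counts are monotone", {
  inst <- tiny_instance(61, n = 10, p = 5, d = 3)
  g1 <- default_gamma1_grid(inst$X, 8)
  g2 <- default_gamma2_grid(inst$X, 8)
  tr1 <- tune_iscc(inst$X, inst$E, inst$z, g1, g2, mode = "known",
                   K = 3, p_target = 3)
  tr2 <- tune_iscc(inst$X, inst$E, inst$z, g1, g2, mode = "known",
                   K = 3, p_target = 3)
  expect_identical(tr1$path, tr2$path)
  expect_identical(c(tr1$gamma1, tr1$gamma2), c(tr2$gamma1, tr2$gamma2))
  # nclust non-increasing along the first gamma1 sweep (up to readout noise)
  sweep1 <- tr1$path[tr1$path$round == 1 & tr1$path$sweep == "gamma1", ]
  expect_true(all(diff(sweep1$nclust) <= 0))
  # pact non-increasing along the gamma2 sweep at fixed gamma1
  sweep2 <- tr1$path[tr1$path$round == 1 & tr1$path$sweep == "gamma2", ]
  expect_true(all(diff(sweep2$pact) <= 0))
})

test_that("BIC mode picks a penalty pair on the grid", {
  inst <- tiny_instance(62, n = 12, p = 4, d = 3)
  tr <- tune_iscc(inst$X, inst$E, inst$z,
                  default_gamma1_grid(inst$X, 6),
                  default_gamma2_grid(inst$X, 6),
                  mode = "bic", max_rounds = 4)
  expect_true(tr$gamma1 %in% tr$path$gamma1)
  expect_true(tr$gamma2 %in% tr$path$gamma2)
  expect_true(is.finite(bic_cluster(inst$X, tr$fit)))
})
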