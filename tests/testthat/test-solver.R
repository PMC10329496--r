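test_that("group soft threshold matches its closed form", {
  v <- c(3, 4)
  expect_equal(group_soft_threshold(v, 0), v)          # tau = 0: identity
  expect_equal(group_soft_threshold(v, 1), c(2.4, 3.2))
  expect_identical(group_soft_threshold(v, 5), c(0, 0))  # ||v|| <= tau
  expect_identical(group_soft_threshold(v, 7), c(0, 0))
  # subgradient optimality of the prox: u + tau*u/||u|| = v at u != 0
  u <- group_soft_threshold(v, 1)
  expect_equal(u + 1 * u / sqrt(sum(u^2)), v)
})

test_that("zero penalties return the data matrix bit-exactly", {
  set.seed(21)
  X <- matrix(rnorm(40), 8, 5)
  E <- build_edge_set(X, d = 3)
  fit <- ama_fit(X, E, NULL, solver_config(0, 0))
  expect_identical(unname(fit$U), unname(X))
  expect_identical(fit$n_selected, ncol(X))
})

test_that("a large enough sparsity penalty kills every feature", {
  set.seed(22)
  X <- scale(matrix(rnorm(60), 10, 6), scale = FALSE)
  z <- rep(c(0.5, 1), 3)
  E <- build_edge_set(X, d = 3)
  g2_kill <- max(sqrt(colSums(X^2))) / min(z)
  fit <- ama_fit(X, E, z, solver_config(gamma1 = 0, gamma2 = g2_kill))
  expect_identical(fit$n_selected, 0L)
  expect_true(all(fit$U == 0))
})

test_that("AMA reaches the optimum of an independent generic minimizer", {
  for (seed in 1:3) {
    inst <- tiny_instance(seed, n = 6, p = 4)
    for (gam in list(c(0.5, 0.3), c(1.5, 0.8))) {
      fit <- ama_fit(inst$X, inst$E, inst$z,
                     solver_config(gam[1], gam[2], tol = 1e-9,
                                   max_iter = 50000))
      U_star <- scc_oracle_minimize(inst$X, inst$E, inst$z, gam[1], gam[2])
      f_ama <- scc_objective(inst$X, fit$U, inst$E, inst$z, gam[1], gam[2])
      f_orc <- scc_objective(inst$X, U_star, inst$E, inst$z, gam[1], gam[2])
      expect_equal(f_ama, f_orc, tolerance = 1e-4)
    }
  }
})

test_that("the dual objective trace is non-decreasing", {
  for (seed in c(7, 19)) {
    set.seed(seed)
    X <- scale(matrix(rnorm(200), 20, 10), scale = FALSE)
    E <- build_edge_set(X, d = 4)
    fit <- ama_fit(X, E, rep(1, 10), solver_config(1, 0.5))
    dt <- fit$dual_trace
    expect_gte(min(diff(dt)), -1e-8 * max(1, max(abs(dt))))
    # and the solution improves on the trivial U = X primal value
    f_fit <- scc_objective(X, fit$U, E, rep(1, 10), 1, 0.5)
    f_X <- scc_objective(X, X, E, rep(1, 10), 1, 0.5)
    expect_lte(f_fit, f_X)
  }
})

test_that("weights of one reduce to plain (sparse) convex clustering", {
  inst <- tiny_instance(31, n = 8, p = 5, d = 3)
  f_null <- ama_fit(inst$X, inst$E, NULL, solver_config(0.8, 0.4))
  f_ones <- ama_fit(inst$X, inst$E, rep(1, 5), solver_config(0.8, 0.4))
  expect_identical(f_null$U, f_ones$U)
  # gamma2 = 0: no feature ever removed regardless of z
  f_g20 <- ama_fit(inst$X, inst$E, inst$z, solver_config(0.8, 0))
  expect_identical(f_g20$n_selected, 5L)
})

test_that("permuting samples permutes the clustering identically", {
  set.seed(40)
  X <- rbind(matrix(rnorm(30, 0), 6, 5), matrix(rnorm(30, 4), 6, 5))
  X <- scale(X, scale = FALSE)
  perm <- sample(nrow(X))
  cfg <- solver_config(gamma1 = 3, gamma2 = 0.2)
  f1 <- ama_fit(X, build_edge_set(X, d = 3), NULL, cfg)
  f2 <- ama_fit(X[perm, ], build_edge_set(X[perm, ], d = 3), NULL, cfg)
  expect_equal(adjusted_rand_index(f1$labels[perm], f2$labels), 1)
})

test_that("cluster readout is the connected components of fused edges", {
  # 3 samples, edge (1,2) fused, edge (2,3) not
  fit <- list(U = matrix(0, 3, 2),
              V = rbind(c(0, 0), c(2, 1)), eps_fuse = 1e-3)
  E <- list(edges = cbind(c(1L, 2L), c(2L, 3L)), w = c(1, 1))
  expect_identical(extract_clusters(fit, E), c(1L, 1L, 2L))
  # no edges: all singletons
  E0 <- list(edges = matrix(integer(0), 0, 2), w = numeric(0))
  expect_identical(extract_clusters(fit, E0), 1:3)
  # everything fused on a connected graph: one cluster
  fit2 <- list(U = matrix(0, 3, 2), V = matrix(0, 2, 2), eps_fuse = 1e-3)
  expect_identical(extract_clusters(fit2, E), c(1L, 1L, 1L))
})

test_that("an empty edge set is only valid without a fusion penalty", {
  X <- matrix(rnorm(12), 6, 2)
  E0 <- list(edges = matrix(integer(0), 0, 2), w = numeric(0))
  expect_error(ama_fit(X, E0, NULL, solver_config(gamma1 = 1)), "empty edge")
  f <- ama_fit(X, E0, NULL, solver_config(0, 0))
  expect_identical(f$labels, 1:6)
})
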