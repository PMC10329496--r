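test_that("spherical settings have the declared dimensions and masks", {
  sim <- simulate_dataset(simulation_spec("S1", seed = 1))
  expect_equal(vapply(sim$blocks, function(b) dim(b$matrix), integer(2)),
               cbind(c(80L, 100L), c(80L, 200L)))
  expect_identical(sum(sim$informative_mask), 60L)
  expect_identical(sum(sim$noisy_mask), 40L)
  expect_false(any(sim$informative_mask & sim$noisy_mask))
  expect_identical(which(sim$informative_mask), c(1:30, 101:130))
  expect_identical(which(sim$noisy_mask), c(31:50, 131:150))
  expect_identical(as.integer(table(sim$true_labels)), rep(20L, 4))

  sim2 <- simulate_dataset(simulation_spec("S2", seed = 1))
  expect_equal(ncol(sim2$blocks[[1]]$matrix), 200)
  expect_equal(ncol(sim2$blocks[[2]]$matrix), 500)
  expect_identical(sum(sim2$informative_mask), 60L)
  expect_identical(sum(sim2$noisy_mask), 40L)
  # S2 flips the second-direction means
  m2 <- colMeans(sim2$blocks[[1]]$matrix[sim2$true_labels == 2, 11:20])
  expect_true(all(m2 < 0))

  # correct weights are 0.5 exactly on the informative set
  expect_identical(sim$z_true$z, ifelse(sim$informative_mask, 0.5, 1))
})

test_that("informative cluster means match the design (CLT check)", {
  # mean of feature 1 in cluster 1 is 3 (block 1, sigma = 0.5)
  reps <- vapply(1:200, function(r) {
    sim <- simulate_dataset(simulation_spec("S1", seed = 1000 + r))
    mean(sim$blocks[[1]]$matrix[sim$true_labels == 1, 1])
  }, 0)
  se <- 0.5 / sqrt(20 * 200)
  expect_lt(abs(mean(reps) - 3), 3 * se)
  # noisy feature 31 has mean 2 in cluster 1 and 0 in clusters 3-4
  sim <- simulate_dataset(simulation_spec("S1", seed = 3))
  expect_equal(mean(sim$blocks[[1]]$matrix[sim$true_labels == 1, 31]), 2,
               tolerance = 0.2)
  expect_equal(mean(sim$blocks[[1]]$matrix[sim$true_labels >= 3, 31]), 0,
               tolerance = 0.2)
})

test_that("half-moon pairs trace the two interlocking arcs", {
  sim <- simulate_dataset(simulation_spec("S3", seed = 5))
  expect_identical(sum(sim$informative_mask), 20L)
  expect_identical(sum(sim$noisy_mask), 20L)
  expect_identical(which(sim$informative_mask), c(1:10, 101:110))
  b <- sim$blocks[[1]]$matrix
  # cluster 1 arcs live on the unit circle around (0,0): radius ~ 1
  r1 <- sqrt(b[sim$true_labels == 1, 1]^2 + b[sim$true_labels == 1, 2]^2)
  expect_equal(mean(r1), 1, tolerance = 0.1)
  # cluster 2 arcs are the reflected moon around (1, 1/2)
  r2 <- sqrt((1 - b[sim$true_labels == 2, 1])^2 +
             (0.5 - b[sim$true_labels == 2, 2])^2)
  expect_equal(mean(r2), 1, tolerance = 0.1)
  # moons sit in y >= -noise and y <= 1/2 + noise respectively
  expect_gt(min(b[sim$true_labels == 1, 2]), -0.5)
  expect_lt(max(b[sim$true_labels == 2, 2]), 1)
})

test_that("noiseless moons form one kNN component per arc", {
  # the arc parametrization endpoints: t = 0 gives (1, 0) on moon 1 and
  # (0, 1/2) on moon 2
  expect_equal(c(cos(0), sin(0)), c(1, 0))
  expect_equal(c(1 - cos(0), 0.5 - sin(0)), c(0, 0.5))
  # in the noiseless limit the two arcs interlock at a 0.5 gap, so once
  # the arcs are sampled densely enough the d = 5 kNN graph connects
  # along each moon but never across
  set.seed(17)
  lab <- rep(1:2, each = 100)
  t <- runif(200, 0, pi)
  X <- cbind(ifelse(lab == 1, cos(t), 1 - cos(t)),
             ifelse(lab == 1, sin(t), 0.5 - sin(t)))
  E <- build_edge_set(X, d = 5)
  g <- igraph::graph_from_edgelist(E$edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  expect_equal(max(comp), 2)
  expect_equal(adjusted_rand_index(comp, lab), 1)
})

test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- simulate_dataset(simulation_spec("S1", theta_both = 0.8, seed = 99))
  s2 <- simulate_dataset(simulation_spec("S1", theta_both = 0.8, seed = 99))
  expect_identical(s1$blocks[[1]]$matrix, s2$blocks[[1]]$matrix)
  expect_identical(s1$z_given$z, s2$z_given$z)
  s3 <- simulate_dataset(simulation_spec("S1", theta_both = 0.8, seed = 100))
  expect_false(identical(s3$blocks[[1]]$matrix, s1$blocks[[1]]$matrix))
})

test_that("weight corruption flips the exact advertised counts", {
  sim <- simulate_dataset(simulation_spec("S1", seed = 12))
  z_true <- sim$z_true
  inf <- sim$informative_mask

  # theta = 1 is the identity
  expect_identical(corrupt_weights(z_true, inf)$z, z_true$z)
  # theta_i = 0: every informative feature loses its favourable weight
  set.seed(1)
  expect_true(all(corrupt_weights(z_true, inf, theta_i = 0)$z == 1))
  # theta_both = 0.7: ceil(0.3 * 60) informative and ceil(0.3 * 240)
  # noninformative flips
  set.seed(2)
  zb <- corrupt_weights(z_true, inf, theta_both = 0.7)$z
  expect_identical(sum(zb[inf] == 1), as.integer(ceiling(0.3 * 60)))
  expect_identical(sum(zb[!inf] == 0.5), as.integer(ceiling(0.3 * 240)))
  # theta_ni only corrupts the noninformative side
  set.seed(3)
  zn <- corrupt_weights(z_true, inf, theta_ni = 0.9)$z
  expect_true(all(zn[inf] == 0.5))
  expect_identical(sum(zn[!inf] == 0.5), as.integer(ceiling(0.1 * 240)))

  expect_error(corrupt_weights(z_true, inf, theta_i = 0.5, theta_ni = 0.5),
               "at most one")
  expect_error(simulation_spec("S1", theta_i = 0.5, theta_both = 0.7),
               "at most one")
})

test_that("replicate studies are deterministic and scc forces unit weights", {
  spec <- simulation_spec("S1", seed = 400)
  ctl <- solver_config(max_iter = 500, tol = 1e-3)
  st1 <- run_replicates(spec, "iscc", R = 1, grid_length = 6, control = ctl)
  st2 <- run_replicates(spec, "iscc", R = 1, grid_length = 6, control = ctl)
  expect_identical(st1$replicates, st2$replicates)
  # with theta_i = 1 and all-correct weights, iscc and scc differ only in z
  st3 <- run_replicates(spec, "scc", R = 1, grid_length = 6, control = ctl)
  expect_identical(st1$replicates$seed, st3$replicates$seed)
  km <- run_replicates(spec, "kmeans", R = 2)
  expect_identical(nrow(km$replicates), 2L)
  expect_true(all(km$replicates$ari >= -1 & km$replicates$ari <= 1))
})
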