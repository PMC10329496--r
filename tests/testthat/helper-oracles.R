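# Independent oracles used across the tests. These deliberately avoid the
# package's own solver/metric code paths.

# primal objective of the sparse convex clustering problem
scc_objective <- function(X, U, E, z, gamma1, gamma2) {
  loss <- 0.5 * sum((X - U)^2)
  fuse <- 0
  if (nrow(E$edges) > 0) {
    D <- U[E$edges[, 1], , drop = FALSE] - U[E$edges[, 2], , drop = FALSE]
    fuse <- sum(E$w * sqrt(rowSums(D^2)))
  }
  grp <- sum(z * sqrt(colSums(U^2)))
  loss + gamma1 * fuse + gamma2 * grp
}

# generic minimizer: BFGS on an epsilon-smoothed objective with
# continuation; independent of the AMA dual-ascent path
scc_oracle_minimize <- function(X, E, z, gamma1, gamma2) {
  n <- nrow(X); p <- ncol(X)
  e1 <- E$edges[, 1]; e2 <- E$edges[, 2]; w <- E$w
  m <- length(w)
  make_fn <- function(eps) {
    list(
      fn = function(u) {
        U <- matrix(u, n, p)
        loss <- 0.5 * sum((X - U)^2)
        fuse <- if (m > 0) {
          D <- U[e1, , drop = FALSE] - U[e2, , drop = FALSE]
          sum(w * sqrt(rowSums(D^2) + eps^2))
        } else 0
        grp <- sum(z * sqrt(colSums(U^2) + eps^2))
        loss + gamma1 * fuse + gamma2 * grp
      },
      gr = function(u) {
        U <- matrix(u, n, p)
        G <- U - X
        if (m > 0) {
          D <- U[e1, , drop = FALSE] - U[e2, , drop = FALSE]
          s <- gamma1 * w / sqrt(rowSums(D^2) + eps^2)
          for (l in seq_len(m)) {
            G[e1[l], ] <- G[e1[l], ] + s[l] * D[l, ]
            G[e2[l], ] <- G[e2[l], ] - s[l] * D[l, ]
          }
        }
        cn <- sqrt(colSums(U^2) + eps^2)
        G <- G + sweep(U, 2, gamma2 * z / cn, "*")
        as.vector(G)
      }
    )
  }
  u <- as.vector(X)
  for (eps in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    f <- make_fn(eps)
    u <- optim(u, f$fn, f$gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
  }
  matrix(u, n, p)
}

# pair-counting adjusted Rand index (Hubert-Arabie via the 2x2 pair
# confusion), independent of the contingency-table implementation
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  sa <- outer(a, a, "==")[upper.tri(diag(n))]
  sb <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(sa & sb); n10 <- sum(sa & !sb)
  n01 <- sum(!sa & sb); n00 <- sum(!sa & !sb)
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# small random instance shared by solver/tuning tests
tiny_instance <- function(seed = 1, n = 6, p = 4, d = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X), "-")
  E <- build_edge_set(X, d = d, phi = 0.5)
  z <- rep(c(0.5, 1), length.out = p)
  list(X = X, E = E, z = z)
}
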