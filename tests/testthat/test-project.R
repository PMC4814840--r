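test_that("PCA matches an independent eigendecomposition oracle", {
  set.seed(1)
  X <- matrix(rnorm(50 * 6), 50, 6)
  m <- pca_fit(X)
  cv <- crossprod(scale(X, scale = FALSE)) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  expect_equal(m$axis_scores, eg$values / sum(eg$values), tolerance = 1e-8)
  expect_lt(max(abs(abs(m$basis) - abs(eg$vectors))), 1e-8)
  # second independent route: svd of the centred matrix
  sv <- svd(scale(X, scale = FALSE))
  expect_equal(m$axis_scores, sv$d^2 / sum(sv$d^2), tolerance = 1e-8)
  # basis is orthonormal and sign-fixed
  expect_lt(max(abs(crossprod(m$basis) - diag(6))), 1e-8)
  for (j in 1:6) expect_gt(m$basis[which.max(abs(m$basis[, j])), j], 0)
  expect_true(all(diff(m$axis_scores) <= 1e-12))
})

test_that("axis-aligned covariance gives the closed-form leading component", {
  set.seed(2)
  X <- cbind(rnorm(4000, sd = 2), rnorm(4000, sd = 1))
  m <- pca_fit(X)
  expect_gt(abs(m$basis[1, 1]), 0.99)          # PC1 ~ (1, 0)
  expect_equal(m$axis_scores[1], 0.8, tolerance = 0.02)
})

test_that("the full-rank PCA rotation preserves pairwise distances", {
  set.seed(3)
  X <- matrix(runif(30 * 5), 30, 5)
  m <- pca_fit(X)
  sc <- pca_transform(m, X)
  expect_equal(as.vector(dist(sc)), as.vector(dist(X)), tolerance = 1e-8)
  # the fitted mean projects to the origin
  mu <- matrix(colMeans(X), 1)
  expect_lt(max(abs(pca_transform(m, mu))), 1e-10)
  # explicit loop-product oracle
  i <- 4
  oracle <- as.numeric((X[i, ] - colMeans(X)) %*% m$basis)
  expect_equal(as.vector(sc[i, ]), oracle, tolerance = 1e-12)
  expect_error(pca_fit(matrix(5, 10, 2), standardise = TRUE), "constant")
})

test_that("LDA recovers the closed-form Fisher direction", {
  set.seed(4)
  n <- 200
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(3, 0), "+"))
  g <- rep(c("a", "b"), each = n)
  m <- lda_fit(X, g, shrinkage = 0)
  expect_equal(ncol(m$basis), 1)
  Sw <- crossprod(scale(X[1:n, ], scale = FALSE)) +
    crossprod(scale(X[-(1:n), ], scale = FALSE))
  w_ref <- solve(Sw, colMeans(X[-(1:n), ]) - colMeans(X[1:n, ]))
  ang <- acos(min(abs(sum(m$basis[, 1] * w_ref)) /
                    sqrt(sum(m$basis[, 1]^2) * sum(w_ref^2)), 1)) * 180 / pi
  expect_lt(ang, 2)
  # MASS as a second, independent implementation
  skip_if_not_installed("MASS")
  ml <- MASS::lda(X, g)
  angm <- acos(min(abs(sum(m$basis[, 1] * ml$scaling)) /
                     sqrt(sum(m$basis[, 1]^2) * sum(ml$scaling^2)), 1)) *
    180 / pi
  expect_lt(angm, 2)
})

test_that("n groups yield exactly n - 1 canonical variables", {
  set.seed(5)
  X <- matrix(rnorm(90 * 4), 90, 4)
  X[31:60, 1] <- X[31:60, 1] + 3
  X[61:90, 2] <- X[61:90, 2] + 3
  g <- rep(c("a", "b", "c"), each = 30)
  m <- lda_fit(X, g)
  expect_equal(ncol(m$basis), 2)
  expect_equal(length(m$axis_scores), 2)
  m2 <- lda_fit(X[1:60, ], g[1:60])
  expect_equal(ncol(m2$basis), 1)
})

test_that("identical groups produce a flagged degenerate model", {
  X <- matrix(rnorm(40), 20, 2)
  g <- rep(c("a", "b"), 10)
  Xd <- rbind(X[g == "a", ], X[g == "a", ])   # literally identical groups
  gd <- rep(c("a", "b"), each = 10)
  m <- lda_fit(Xd, gd)
  expect_true(m$degenerate)
  expect_true(all(m$axis_scores == 0))
  expect_error(lda_fit(X[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("canonical variables are invariant to invertible linear maps", {
  set.seed(6)
  n <- 60
  X <- rbind(matrix(rnorm(3 * n), n, 3),
             sweep(matrix(rnorm(3 * n), n, 3), 2, c(2, 1, 0), "+"))
  g <- rep(c("a", "b"), each = n)
  sc1 <- drop(pca_transform(lda_fit(X, g, shrinkage = 0, pca_var = 1,
                                    standardise = FALSE), X))
  for (rep in 1:3) {
    A <- matrix(rnorm(9), 3, 3) + diag(3) * 2
    sc2 <- drop(pca_transform(lda_fit(X %*% A, g, shrinkage = 0,
                                      pca_var = 1, standardise = FALSE),
                              X %*% A))
    expect_gt(abs(cor(sc1, sc2)), 1 - 1e-6)
  }
})

test_that("TPP recovers its target subspaces", {
  set.seed(7)
  X <- matrix(rnorm(50 * 6), 50, 6)
  m <- pca_fit(X)
  tgt <- pca_transform(m, X, n_components = 2)
  tp <- tpp_fit(X, tgt)
  expect_gt(min(svd(crossprod(tp$basis, m$basis[, 1:2]))$d), 1 - 1e-6)
  expect_lt(max(abs(crossprod(tp$basis) - diag(2))), 1e-10)
  # planted random orthonormal basis
  B <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  tp2 <- tpp_fit(X, scale(X, scale = FALSE) %*% B)
  expect_lt(tp2$objective, 1e-10)
  expect_gt(min(svd(crossprod(tp2$basis, B))$d), 1 - 1e-6)
})

test_that("TPP with a group-indicator target separates at least as well as PCA", {
  # nuisance variance dominates feature 1, so the top PCA axis ignores
  # the group effect carried by feature 4 - the setting TPP exists for
  set.seed(8)
  n <- 50
  X <- rbind(matrix(rnorm(5 * n), n, 5),
             sweep(matrix(rnorm(5 * n), n, 5), 2, c(0, 0, 0, 2.5, 0), "+"))
  X[, 1] <- X[, 1] * 4
  g <- rep(0:1, each = n)
  tgt <- cbind(g - mean(g))
  tp <- tpp_fit(X, tgt)
  pca <- pca_fit(X)
  sep <- function(sc) {
    sc <- as.matrix(sc)
    m1 <- colMeans(sc[1:n, , drop = FALSE])
    m2 <- colMeans(sc[-(1:n), , drop = FALSE])
    sum((m1 - m2)^2)
  }
  expect_gte(sep(scale(X, scale = FALSE) %*% tp$basis),
             sep(pca_transform(pca, X, 1)))
})

test_that("the KS statistic equals the brute-force sup-ECDF oracle", {
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), mean = runif(1))
    pool <- c(x, y)
    oracle <- max(sapply(pool, function(t)
      abs(mean(x <= t) - mean(y <= t))))
    expect_equal(ks_statistic(x, y), oracle, tolerance = 1e-12)
    expect_equal(ks_statistic(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  }
  expect_equal(ks_statistic(0:2, 10:12), 1)
})

test_that("discriminate_1d ties projection, KS and p-value together", {
  set.seed(10)
  n <- 40
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(4, 0), "+"))
  g <- rep(c("a", "b"), each = n)
  r <- discriminate_1d(X, g)
  expect_gt(r$ks_statistic, 0.8)
  expect_lt(r$p_value, 0.05)
  expect_equal(length(r$scores), 2 * n)
  # identical groups: degenerate projection, D = 0, p = 1
  Xd <- rbind(X[1:n, ], X[1:n, ])
  rd <- discriminate_1d(Xd, g)
  expect_equal(rd$ks_statistic, 0)
  expect_equal(rd$p_value, 1)
  expect_error(discriminate_1d(X, rep(c("a", "b", "c"), length.out = 2 * n)),
               "2 groups")
})

test_that("median KS separation grows with the true effect size", {
  meds <- sapply(c(0, 1, 2.5, 4), function(delta) {
    ks <- sapply(1:40, function(s) {
      d <- make_feature_dataset(25, 4, effect = c(delta, 0, 0, 0),
                                seed = 7000 + 97 * s + round(100 * delta))
      discriminate_1d(dplyr::select(d, -cell_id, -group),
                      d$group)$ks_statistic
    })
    median(ks)
  })
  expect_true(all(diff(meds) >= 0))
})

test_that("RGB rendering maps spectral regions to distinct colours", {
  H <- 30
  cube <- array(0, dim = c(H, 30, 6))
  cube[1:10, , 1] <- 50
  cube[11:20, , 3] <- 50
  cube[21:30, , 5] <- 50
  cube <- cube + array(runif(length(cube)), dim = dim(cube)) *
    (cube > 0)                           # jitter so variance is nonzero
  st <- hyper_stack(cube, channel_table(6))
  pm <- pixel_pca(st)
  rgb <- render_rgb(st, pm)
  expect_true(all(rgb >= 0 & rgb <= 1))
  # the three regions differ in their dominant rendered channel
  doms <- sapply(list(1:10, 11:20, 21:30), function(rows)
    which.max(apply(rgb[rows, , ], 3, mean)))
  expect_equal(length(unique(doms)), 3)
  # all-zero pixels render black
  cube0 <- cube; cube0[1, 1, ] <- 0
  st0 <- hyper_stack(cube0, channel_table(6))
  rgb0 <- render_rgb(st0, pixel_pca(st0))
  expect_equal(as.vector(rgb0[1, 1, ]), c(0, 0, 0))
  # rank-deficient single-endmember stack: PCA keeps < 3 components
  r1 <- array(rep(c(2, 1, 0.5, 0.2, 0.1, 0.1), each = H * 30),
              dim = c(H, 30, 6)) *
    array(runif(H * 30), dim = c(H, 30, 6))[, , rep(1, 6)]
  expect_error(render_rgb(hyper_stack(r1, channel_table(6)),
                          pca_fit(matrix(r1, H * 30, 6))),
               "3 components")
})

test_that("projection models survive a JSON round trip", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  m <- pca_fit(X)
  path <- withr::local_tempfile(fileext = ".json")
  write_projection_model(m, path)
  back <- read_projection_model(path)
  expect_equal(back$basis, m$basis)
  expect_equal(back$kind, "PCA")
  expect_equal(pca_transform(back, X), pca_transform(m, X))
})
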