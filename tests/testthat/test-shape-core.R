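test_that("centroid size matches analytic values, homogeneity and the direct formula", {
  expect_equal(centroid_size(square_config())$centroid_size, sqrt(2))
  expect_equal(centroid_size(square_config())$unit, "pixel")

  # SCALE converts to physical units multiplicatively
  scaled <- square_config(scale = 3)
  expect_equal(centroid_size(scaled)$centroid_size, 3 * sqrt(2))
  expect_equal(centroid_size(scaled)$unit, "physical")

  # independent formula oracle on a random 27-point configuration
  X <- random_config(27, seed = 7)
  cs <- centroid_size(config_tbl(X))$centroid_size
  ctr <- colMeans(X)
  oracle <- sqrt(sum((X[, 1] - ctr[1])^2 + (X[, 2] - ctr[2])^2))
  expect_equal(cs, oracle, tolerance = 1e-12)

  expect_error(centroid_size(config_tbl(X[1:2, ])), "at least 3 landmarks")
})

test_that("GPA aligns identical configurations to coincidence", {
  X <- random_config(10, seed = 1)
  w <- dplyr::bind_rows(lapply(1:4, function(i) config_tbl(X, id = paste0("s", i))))
  fit <- gpa(w)
  D <- procrustes_dist_matrix(fit)
  expect_lt(max(D), 1e-9)
  # every aligned specimen: centroid at origin, unit centroid size
  for (i in 1:4) {
    expect_equal(colMeans(fit$coords[, , i]), c(x = 0, y = 0), tolerance = 1e-8)
    expect_equal(sum(fit$coords[, , i]^2), 1, tolerance = 1e-8)
  }
  # consensus is the arithmetic mean of aligned coordinates
  expect_equal(fit$consensus, apply(fit$coords, c(1, 2), mean), tolerance = 1e-8)
})

test_that("GPA output is invariant to similarity transforms of the raw inputs", {
  set.seed(21)
  X1 <- random_config(12)
  X2 <- X1 + matrix(rnorm(24, sd = 0.05), 12, 2)
  X3 <- X1 + matrix(rnorm(24, sd = 0.05), 12, 2)
  base <- dplyr::bind_rows(config_tbl(X1, "a"), config_tbl(X2, "b"), config_tbl(X3, "c"))
  fit0 <- gpa(base)
  # arbitrary rotation/translation/scaling per specimen
  X1t <- similarity_transform(X1, theta = 1.1, s = 3.7, t = c(10, -4))
  X2t <- similarity_transform(X2, theta = -2.4, s = 0.2, t = c(-1, 8))
  X3t <- similarity_transform(X3, theta = 0.6, s = 12, t = c(0.3, 0.3))
  fit1 <- gpa(dplyr::bind_rows(config_tbl(X1t, "a"), config_tbl(X2t, "b"),
                               config_tbl(X3t, "c")))
  # aligned shapes agree up to one global rotation: compare via distances
  for (i in 1:3) {
    expect_lt(procrustes_distance(fit0$coords[, , i], fit1$coords[, , i]), 1e-6)
  }
})

test_that("two-specimen GPA matches the closed-form optimal rotation and a grid search", {
  set.seed(33)
  A <- random_config(8)
  B <- A + matrix(rnorm(16, sd = 0.1), 8, 2)
  fit <- gpa(dplyr::bind_rows(config_tbl(A, "a"), config_tbl(B, "b")), tol = 1e-14)
  d_gpa <- sqrt(sum((fit$coords[, , 1] - fit$coords[, , 2])^2))

  # closed-form full Procrustes distance (complex inner product)
  d_closed <- procrustes_distance(A, B)
  # grid-search oracle at 0.0001-radian resolution
  d_grid <- grid_procrustes_distance(A, B, n_grid = ceiling(2 * pi / 1e-4))
  expect_equal(d_closed, d_grid, tolerance = 1e-6)
  # partial-fit distance between two unit-scaled aligned shapes is bounded
  # below by the full Procrustes distance and agrees closely for small shapes
  expect_equal(d_gpa, d_grid, tolerance = 1e-2)
  expect_gte(d_gpa, d_closed - 1e-12)
})

test_that("GPA consensus minimizes the summed squared deviation (stochastic)", {
  sim <- simulate_wings(n_groups = 2, n_per_group = 5, seed = 13)
  fit <- gpa(sim$wings)
  Q0 <- sum(apply(fit$coords, 3, function(X) sum((X - fit$consensus)^2)))
  set.seed(99)
  for (r in 1:20) {
    pert <- fit$consensus + matrix(rnorm(54, sd = 0.005), 27, 2)
    Q <- sum(apply(fit$coords, 3, function(X) sum((X - pert)^2)))
    expect_gte(Q, Q0)
  }
})

test_that("GPA is permutation-equivariant in specimen order when not sliding", {
  sim <- simulate_wings(n_groups = 2, n_per_group = 4, seed = 17)
  fit <- gpa(sim$wings)
  ids <- unique(sim$wings$specimen)
  perm <- rev(ids)
  w2 <- sim$wings[order(match(sim$wings$specimen, perm)), ]
  fit2 <- gpa(w2)
  expect_equal(fit2$consensus, fit$consensus, tolerance = 1e-6)
  for (s in ids) {
    expect_equal(fit2$coords[, , s], fit$coords[, , s], tolerance = 1e-6)
  }
})

test_that("semilandmark sliding is a descent step and finds orthogonal projections", {
  # straight-segment construction: curve points on a line, consensus point
  # displaced off the line; Procrustes-criterion sliding must move the
  # point to the orthogonal projection of the consensus point
  fixed <- rbind(c(0, 0), c(10, 0))
  semi <- c(4, 1)                       # off its optimal spot along y = 0... slid along tangent x
  X <- rbind(fixed[1, ], semi, fixed[2, ])
  cons <- rbind(fixed[1, ], c(6, 2), fixed[2, ])
  slid <- wingmorph:::slide_one(X, cons, chain = c(1L, 2L, 3L), semi_idx = 2L,
                                criterion = "procrustes", Be = NULL)
  # tangent is along x; orthogonal projection of (6,2) onto the line y = 1
  # through (4,1) is (6,1)
  expect_equal(unname(slid[2, ]), c(6, 1), tolerance = 1e-10)

  # tangent grid search oracle
  ts <- seq(-5, 5, by = 1e-4)
  obj <- vapply(ts, function(t) sum((c(4 + t, 1) - cons[2, ])^2), 0)
  expect_equal(unname(slid[2, 1]), 4 + ts[which.min(obj)], tolerance = 1e-3)

  # already-optimal semilandmarks do not move (consensus == configuration)
  slid0 <- wingmorph:::slide_one(X, X, chain = c(1L, 2L, 3L), semi_idx = 2L,
                                 criterion = "procrustes", Be = NULL)
  expect_equal(slid0, X, tolerance = 1e-12)
})

test_that("bending-energy sliding never increases the bending objective", {
  sim <- simulate_wings(n_groups = 1, n_per_group = 4, seed = 23)
  fit <- gpa(sim$wings)           # aligned, unslid
  cons <- fit$consensus
  Be <- wingmorph:::bending_energy_matrix(cons)
  K <- kronecker(Be, diag(2))
  lms <- fit$landmarks
  chain <- match(c(4L, 22:27, 13L), lms)
  semi_idx <- match(22:27, lms)
  bend_obj <- function(X) {
    v <- as.vector(t(X)) - as.vector(t(cons))
    as.numeric(crossprod(v, K %*% v))
  }
  for (i in 1:4) {
    X <- fit$coords[, , i]
    Xs <- wingmorph:::slide_one(X, cons, chain, semi_idx, "bending", Be)
    expect_lte(bend_obj(Xs), bend_obj(X) + 1e-12)
    # only semilandmarks moved
    expect_equal(Xs[-semi_idx, ], X[-semi_idx, ])
  }
  # procrustes-criterion sliding likewise never increases its objective
  for (i in 1:4) {
    X <- fit$coords[, , i]
    Xs <- wingmorph:::slide_one(X, cons, chain, semi_idx, "procrustes", Be = NULL)
    expect_lte(sum((Xs - cons)^2), sum((X - cons)^2) + 1e-12)
  }
})

test_that("full Procrustes distance has metric properties and matches brute force", {
  set.seed(4)
  A <- random_config(9)
  B <- random_config(9)
  expect_lt(procrustes_distance(A, A), 1e-7)
  expect_equal(procrustes_distance(A, B), procrustes_distance(B, A), tolerance = 1e-12)
  expect_lt(procrustes_distance(A, similarity_transform(A, 0.8, 4, c(2, 3))), 1e-7)
  expect_error(procrustes_distance(A, matrix(1, 9, 2)), "degenerate")

  # brute-force oracle, 1e5-step rotation grid
  expect_equal(procrustes_distance(A, B),
               grid_procrustes_distance(A, B, n_grid = 1e5), tolerance = 1e-6)

  # triangle inequality on sampled aligned unit-size triples
  sim <- simulate_wings(n_groups = 3, n_per_group = 3, seed = 31)
  fit <- gpa(sim$wings)
  D <- procrustes_dist_matrix(fit)
  n <- nrow(D)
  for (r in 1:30) {
    ijk <- sample(n, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("mean shapes equal independent per-landmark summation", {
  sim <- simulate_wings(n_groups = 2, n_per_group = 5, seed = 19)
  fit <- gpa(sim$wings)
  g1 <- sim$metadata$specimen[sim$metadata$group == "G01"]
  ms <- mean_shape(fit, g1)
  # independent summation oracle
  idx <- which(fit$specimens %in% g1)
  acc <- matrix(0, 27, 2)
  for (i in idx) acc <- acc + fit$coords[, , i]
  expect_equal(as.matrix(ms[, c("x", "y")]), acc / length(idx),
               ignore_attr = TRUE, tolerance = 1e-12)

  # mean of identical shapes is that shape
  X <- fit$coords[, , 1]
  w <- dplyr::bind_rows(config_tbl(X, "a"), config_tbl(X, "b"))
  f2 <- gpa(w)
  ms2 <- mean_shape(f2)
  expect_lt(procrustes_distance(as.matrix(ms2[, c("x", "y")]), X), 1e-8)

  # mean of a shape and its point-reflection through the consensus is the consensus
  cons <- fit$consensus
  dev <- fit$coords[, , 1] - cons
  m <- (cons + dev + (cons - dev)) / 2
  expect_equal(m, cons, tolerance = 1e-12)

  expect_error(mean_shape(fit, "no_such_specimen"), "no specimens match")
})

test_that("thin-plate-spline estimation restores deleted landmarks exactly and affinely", {
  ref <- wing_template()
  # nothing missing -> unchanged
  w <- config_tbl(ref, "complete")
  out <- estimate_missing(w, ref)
  expect_equal(out$x, w$x)
  expect_false(any(out$estimated))

  # a configuration equal to the reference with one landmark deleted:
  # the interpolant restores it exactly
  w2 <- config_tbl(ref, "gap")
  w2$missing[10] <- TRUE
  w2$x[10] <- NA; w2$y[10] <- NA
  out2 <- estimate_missing(w2, ref)
  expect_equal(out2$x[10], ref[10, 1], tolerance = 1e-8)
  expect_equal(out2$y[10], ref[10, 2], tolerance = 1e-8)
  expect_true(out2$estimated[10])

  # affine oracle: a purely affine deformation has zero bending, so TPS
  # estimation of a deleted landmark equals its affine image
  Aff <- matrix(c(1.2, 0.3, -0.1, 0.9), 2, 2)
  shift <- c(0.5, -1)
  def <- sweep(ref %*% Aff, 2, shift, "+")
  w3 <- config_tbl(def, "affine")
  w3$missing[5] <- TRUE
  w3$x[5] <- NA; w3$y[5] <- NA
  out3 <- estimate_missing(w3, ref)
  truth <- ref[5, ] %*% Aff + shift
  expect_equal(out3$x[5], truth[1], tolerance = 1e-6)
  expect_equal(out3$y[5], truth[2], tolerance = 1e-6)

  # degenerate inputs refuse
  w4 <- config_tbl(ref, "gone")
  w4$missing <- TRUE
  expect_error(estimate_missing(w4, ref), "at least 3 observed")
})

test_that("mirroring commutes with scale application", {
  w <- square_config(scale = 2.5)
  a <- mirror_wings(w)
  a_arr <- wings_to_array(a, apply_scale = TRUE)
  b_arr <- wings_to_array(w, apply_scale = TRUE)
  b <- array_to_wings(b_arr)
  b <- mirror_wings(dplyr::mutate(b, side = "left"))
  expect_equal(as.vector(a_arr[, 1, 1]), b$x, tolerance = 1e-12)
})

test_that("squared full Procrustes distance matches vegan's symmetric Procrustes SS", {
  skip_if_not_installed("vegan")
  # vegan solves the same superimposition independently (SVD-based); for
  # nearby shapes (no reflection ambiguity) its symmetric sum of squares
  # equals the squared full Procrustes distance
  set.seed(91)
  for (r in 1:5) {
    A <- random_config(12)
    B <- A + matrix(rnorm(24, sd = 0.1), 12, 2)
    d2 <- procrustes_distance(A, B)^2
    ss <- vegan::procrustes(A, B, symmetric = TRUE)$ss
    expect_equal(d2, ss, tolerance = 1e-9)
  }
})
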