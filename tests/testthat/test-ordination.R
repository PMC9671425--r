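test_that("shape PCA matches a brute-force covariance eigensolve", {
  sim <- simulate_wings(n_groups = 2, n_per_group = 6, seed = 3)
  fit <- gpa(sim$wings)
  pc <- shape_pca(fit)
  expect_false(is.unsorted(rev(pc$variance_fraction)))
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-10)

  Y <- wingmorph:::flatten_coords(fit$coords)
  ev <- eigen(stats::cov(Y), symmetric = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  expect_equal(pc$sdev^2, ev, tolerance = 1e-8)
})

test_that("rank-one variation loads entirely on PC1", {
  X <- wing_template()
  d <- matrix(0, 27, 2); d[5, 1] <- 0.05
  w <- dplyr::bind_rows(lapply(1:6, function(i) config_tbl(X + i * d, paste0("s", i))))
  fit <- gpa(w)
  pc <- shape_pca(fit)
  expect_gt(pc$variance_fraction[1], 0.999)
})

test_that("CVA recovers the separating direction of a two-group construction", {
  sim <- simulate_wings(n_groups = 2, n_per_group = 60, group_effect = 0.08,
                        noise_sd = 0.01, seed = 9)
  fit <- gpa(sim$wings)
  # retain a small, well-conditioned subspace: with isotropic noise the
  # estimated within covariance in trailing PCs is noisy and its inverse
  # would tilt the axis away from the mean difference
  model <- cva(fit, "group", data = sim$metadata, retain = 4)
  expect_equal(ncol(model$axes), 1)

  # CV1, mapped back to shape space, must be nearly parallel to the
  # difference of the two group mean shapes
  Y <- wingmorph:::flatten_coords(fit$coords)
  lab <- sim$metadata$group[match(fit$specimens, sim$metadata$specimen)]
  md <- colMeans(Y[lab == "G01", ]) - colMeans(Y[lab == "G02", ])
  ax <- model$shape_axes[, 1]
  cosang <- abs(sum(md * ax)) / sqrt(sum(md^2) * sum(ax^2))
  expect_gt(cosang, 0.99)
})

test_that("canonical scores have identity pooled within-group covariance", {
  sim <- simulate_wings(n_groups = 4, n_per_group = 10, seed = 10)
  fit <- gpa(sim$wings)
  model <- cva(fit, "group", data = sim$metadata)
  expect_equal(ncol(model$axes), 3)
  expect_equal(sum(model$explained_variance_fractions), 1, tolerance = 1e-10)

  S <- as.matrix(model$scores[, paste0("CV", 1:3)])
  lab <- model$scores$group
  W <- matrix(0, 3, 3)
  for (g in unique(lab)) {
    Sg <- S[lab == g, , drop = FALSE]
    W <- W + crossprod(sweep(Sg, 2, colMeans(Sg)))
  }
  W <- W / (nrow(S) - length(unique(lab)))
  expect_equal(W, diag(3), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("canonical axes maximize the among/within variance ratio", {
  sim <- simulate_wings(n_groups = 3, n_per_group = 8, seed = 6)
  fit <- gpa(sim$wings)
  model <- cva(fit, "group", data = sim$metadata, retain = 10)
  Y <- wingmorph:::flatten_coords(fit$coords)
  Z <- sweep(Y, 2, model$center) %*% model$rotation
  lab <- sim$metadata$group[match(fit$specimens, sim$metadata$specimen)]
  ratio <- function(a) {
    s <- drop(Z %*% a)
    m <- tapply(s, lab, mean)
    within <- sum((s - m[lab])^2)
    among <- sum(table(lab) * (m - mean(s))^2)
    among / within
  }
  r_cv1 <- ratio(model$axes[, 1])
  set.seed(77)
  for (i in 1:200) {
    a <- rnorm(10)
    expect_lte(ratio(a), r_cv1 + 1e-8)
  }
})

test_that("CVA agrees with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  sim <- simulate_wings(n_groups = 3, n_per_group = 12, seed = 15)
  fit <- gpa(sim$wings)
  model <- cva(fit, "group", data = sim$metadata, retain = 8)
  Y <- wingmorph:::flatten_coords(fit$coords)
  Z <- sweep(Y, 2, model$center) %*% model$rotation
  lab <- sim$metadata$group[match(fit$specimens, sim$metadata$specimen)]
  ld <- MASS::lda(Z, grouping = lab)
  # first discriminant directions collinear
  a1 <- model$axes[, 1]; b1 <- ld$scaling[, 1]
  expect_gt(abs(sum(a1 * b1)) / sqrt(sum(a1^2) * sum(b1^2)), 0.999)

  # classification agreement with equal priors
  pr <- stats::predict(ld, prior = rep(1 / 3, 3))
  ours <- wingmorph:::posterior_from_model(model, Y)
  win <- vapply(split(ours, ours$row), function(d) d$group[which.max(d$posterior)], "")
  expect_gt(mean(win == as.character(pr$class)), 0.97)
})

test_that("errors: small groups and degenerate inputs are refused", {
  sim <- simulate_wings(n_groups = 2, n_per_group = 4, seed = 2)
  fit <- gpa(sim$wings)
  lab <- stats::setNames(rep(c("a", "b"), each = 4), fit$specimens)
  lab[1] <- "solo_group"
  expect_error(cva(fit, lab), "solo_group")
  expect_error(cva(fit, stats::setNames(rep("one", 8), fit$specimens)),
               "at least 2 groups")
})

test_that("LOO cross-validation is perfect for well-separated groups", {
  sim <- simulate_wings(n_groups = 3, n_per_group = 8, group_effect = 0.1,
                        noise_sd = 0.005, seed = 21)
  fit <- gpa(sim$wings)
  conf <- loo_crossvalidate(fit, "group", data = sim$metadata)
  expect_equal(conf$overall_accuracy, 100)
  expect_equal(conf$kappa, 1)
  # rows sum to group sizes
  expect_equal(unname(rowSums(conf$counts)), rep(8, 3))
  expect_true(all(abs(rowSums(conf$percent) - 100) < 0.1))
})

test_that("accuracy and kappa are invariant to group-label permutation", {
  sim <- simulate_wings(n_groups = 3, n_per_group = 7, group_effect = 0.04,
                        noise_sd = 0.012, seed = 22)
  fit <- gpa(sim$wings)
  c1 <- loo_crossvalidate(fit, "group", data = sim$metadata)
  md2 <- sim$metadata
  md2$group <- c(G01 = "zzz", G02 = "aaa", G03 = "mmm")[sim$metadata$group]
  c2 <- loo_crossvalidate(fit, "group", data = md2)
  expect_equal(c2$overall_accuracy, c1$overall_accuracy)
  expect_equal(c2$kappa, c1$kappa)
})

test_that("Cohen's Kappa has its analytic fixed points", {
  expect_equal(cohens_kappa(diag(5) * 7), 1)
  # rows proportional to the column marginal -> chance agreement, kappa 0
  m <- outer(c(10, 20, 30), c(0.2, 0.3, 0.5))
  expect_equal(cohens_kappa(m), 0, tolerance = 1e-12)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "zero total")
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
})

test_that("published nine-subfamily percentages reconstruct counts, accuracy and kappa", {
  pub <- published_classification("nine")
  counts <- confusion_from_percent(pub$percent, pub$class_sizes)
  expect_equal(unname(rowSums(counts)), unname(pub$class_sizes))
  cs <- confusion_summary(counts)
  expect_equal(round(cs$kappa, 2), 0.86)
  expect_equal(round(cs$overall_accuracy, 2), 87.99)
  expect_equal(unname(cs$per_group_accuracy["Ophioninae"]), 100)
})

test_that("posterior classification is normalized, sharp at group means, and rotation-invariant", {
  sim <- simulate_wings(n_groups = 3, n_per_group = 10, group_effect = 0.1,
                        noise_sd = 0.006, seed = 30)
  fit <- gpa(sim$wings)
  model <- cva(fit, "group", data = sim$metadata)

  # a specimen exactly at a group mean with well-separated groups
  lab <- sim$metadata$group[match(fit$specimens, sim$metadata$specimen)]
  Y <- wingmorph:::flatten_coords(fit$coords)
  at_mean <- matrix(colMeans(Y[lab == "G02", ]), 1)
  post <- wingmorph:::posterior_from_model(model, at_mean)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  expect_gt(post$posterior[post$group == "G02"], 0.999)

  # classify_new on raw configurations: posteriors sum to one per specimen
  new_raw <- sim$wings[sim$wings$specimen %in% fit$specimens[1:2], ]
  new_raw$specimen <- paste0(new_raw$specimen, "_new")
  res <- classify_new(model, new_raw, consensus = fit$consensus)
  sums <- tapply(res$posterior, res$specimen, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(res$winner), 2)

  # rotating (and translating/scaling) the raw input does not change posteriors
  rot <- new_raw
  for (s in unique(rot$specimen)) {
    sel <- rot$specimen == s
    M <- similarity_transform(as.matrix(rot[sel, c("x", "y")]), 1.3, 2.5, c(5, -2))
    rot$x[sel] <- M[, 1]; rot$y[sel] <- M[, 2]
  }
  res_rot <- classify_new(model, rot, consensus = fit$consensus)
  expect_equal(res_rot$posterior, res$posterior, tolerance = 1e-6)

  # landmark subset mismatch is refused
  expect_error(classify_new(model, drop_landmarks(new_raw, 22L),
                            consensus = fit$consensus), "mismatch")
})

test_that("between-group PCA distances equal direct mean differences and honest p-values", {
  sim <- simulate_wings(n_groups = 3, n_per_group = 6, group_effect = 0.07,
                        noise_sd = 0.008, seed = 40)
  fit <- gpa(sim$wings)
  bg <- bgpca(fit, "group", data = sim$metadata, n_perm = 300, seed = 2)

  Y <- wingmorph:::flatten_coords(fit$coords)
  lab <- sim$metadata$group[match(fit$specimens, sim$metadata$specimen)]
  for (k in seq_len(nrow(bg$distances))) {
    g1 <- bg$distances$group1[k]; g2 <- bg$distances$group2[k]
    oracle <- sqrt(sum((colMeans(Y[lab == g1, ]) - colMeans(Y[lab == g2, ]))^2))
    expect_equal(bg$distances$distance[k], oracle, tolerance = 1e-12)
  }
  expect_true(all(bg$distances$p_value >= 1 / bg$distances$n_replicates))
  expect_true(all(bg$distances$p_value <= 1))
})

test_that("small-group permutation p-values match exhaustive enumeration", {
  # two tiny groups of 3: all 20 label splits enumerable by hand
  X <- wing_template()
  set.seed(55)
  mk <- function(id, off) config_tbl(X + off + matrix(rnorm(54, sd = 0.01), 27, 2), id)
  d <- matrix(0, 27, 2); d[7, 1] <- 0.06
  w <- dplyr::bind_rows(
    mk("a1", 0), mk("a2", 0), mk("a3", 0),
    mk("b1", d), mk("b2", d), mk("b3", d))
  fit <- gpa(w)
  lab <- stats::setNames(rep(c("A", "B"), each = 3), fit$specimens)
  bg <- bgpca(fit, lab, n_perm = 1000, seed = 3)
  expect_true(bg$distances$exhaustive)
  expect_equal(bg$distances$n_replicates, choose(6, 3))

  # manual enumeration oracle
  Y <- wingmorph:::flatten_coords(fit$coords)
  d_obs <- sqrt(sum((colMeans(Y[1:3, ]) - colMeans(Y[4:6, ]))^2))
  splits <- utils::combn(6, 3)
  d_all <- apply(splits, 2, function(s)
    sqrt(sum((colMeans(Y[s, ]) - colMeans(Y[-s, ]))^2)))
  expect_equal(bg$distances$p_value, mean(d_all >= d_obs - 1e-12))
})

test_that("a fossil placed at a group average has distance zero to it", {
  sim <- simulate_wings(n_groups = 2, n_per_group = 5, seed = 60)
  fit <- gpa(sim$wings)
  Y <- wingmorph:::flatten_coords(fit$coords)
  lab <- sim$metadata$group[match(fit$specimens, sim$metadata$specimen)]

  # append a pseudo-fossil exactly at the G01 average
  arr <- fit$coords
  fake <- matrix(colMeans(Y[lab == "G01", ]), ncol = 2, byrow = TRUE)
  arr2 <- array(c(arr, fake), dim = dim(arr) + c(0, 0, 1),
                dimnames = list(dimnames(arr)[[1]], dimnames(arr)[[2]],
                                c(dimnames(arr)[[3]], "fossil_x")))
  fit2 <- fit; fit2$coords <- arr2; fit2$specimens <- dimnames(arr2)[[3]]
  bg <- bgpca(fit2, stats::setNames(lab, fit$specimens),
              held_out = "fossil_x", n_perm = 100, seed = 1)
  d <- bg$distances
  expect_lt(d$distance[d$group1 == "G01" & d$group2 == "fossil_x"], 1e-10)
})
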