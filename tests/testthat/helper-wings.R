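# Fixtures built in code: small configurations and datasets reused across
# test files.

# a unit square, centroid size sqrt(2)
square_config <- function(id = "sq", scale = NA_real_) {
  tibble::tibble(
    specimen = id, landmark = 1:4,
    x = c(-0.5, 0.5, 0.5, -0.5), y = c(-0.5, -0.5, 0.5, 0.5),
    semilandmark = FALSE, missing = FALSE, scale = scale,
    image = NA_character_, side = "left"
  )
}

# random non-degenerate p-point configuration (matrix)
random_config <- function(p = 27, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(stats::rnorm(p, sd = sd), stats::rnorm(p, sd = sd))
}

config_tbl <- function(X, id = "cfg", semilandmarks = integer()) {
  tibble::tibble(
    specimen = id, landmark = seq_len(nrow(X)),
    x = unname(X[, 1]), y = unname(X[, 2]),
    semilandmark = seq_len(nrow(X)) %in% semilandmarks,
    missing = FALSE, scale = NA_real_,
    image = NA_character_, side = "left"
  )
}

# apply a similarity transform (rotation theta, scale s, translation t)
similarity_transform <- function(X, theta = 0, s = 1, t = c(0, 0)) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  sweep(s * (X %*% R), 2, t, "+")
}

# brute-force full Procrustes distance by rotation grid search:
# both configurations centered and scaled to unit size, then the best
# scale is solved analytically for every grid angle
grid_procrustes_distance <- function(a, b, n_grid = 1e5) {
  center_unit <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2))
  }
  a <- center_unit(a); b <- center_unit(b)
  best <- Inf
  thetas <- seq(0, 2 * pi, length.out = n_grid)
  for (th in thetas) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    br <- b %*% R
    beta <- sum(a * br)          # optimal scale given rotation (||br|| = 1)
    d <- sqrt(sum((a - beta * br)^2))
    if (d < best) best <- d
  }
  best
}
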