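#' Centroid size of each wing configuration
#'
#' Centroid size is the square root of the summed squared distances of all
#' landmarks to their centroid — the standard geometric-morphometric size
#' measure, uncorrelated with shape under isotropic landmark noise. When a
#' specimen carries a digitizing scale it is applied first, so sizes come
#' out in the file's physical unit; specimens without a scale are reported
#' in digitizer (pixel) units and flagged.
#'
#' @param wings A wing landmark tibble.
#' @return A tibble with columns `specimen`, `centroid_size`, `unit`
#'   (`"physical"` or `"pixel"`).
#' @export
centroid_size <- function(wings) {
  check_wing_tbl(wings)
  if (any(wings$missing %||% FALSE)) {
    abort("centroid size is undefined with missing landmarks; drop or estimate them first")
  }
  arr <- wings_to_array(wings, apply_scale = TRUE)
  if (dim(arr)[1] < 3) abort("centroid size needs at least 3 landmarks")
  has_scale <- if ("scale" %in% names(wings)) {
    !is.na(wings$scale[match(dimnames(arr)[[3]], wings$specimen)])
  } else rep(FALSE, dim(arr)[3])
  tibble::tibble(
    specimen = dimnames(arr)[[3]],
    centroid_size = unname(apply(arr, 3, config_centroid_size)),
    unit = unname(ifelse(has_scale, "physical", "pixel"))
  )
}

# optimal rotation-only angle aligning X onto target (both centered)
opt_rotation_angle <- function(X, target) {
  atan2(sum(X[, 1] * target[, 2] - X[, 2] * target[, 1]),
        sum(X[, 1] * target[, 1] + X[, 2] * target[, 2]))
}

rotate_config <- function(X, theta) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  X %*% R
}

#' Generalized Procrustes analysis of wing landmarks
#'
#' Iterative superimposition removing translation, scale and rotation:
#' every configuration is centered and scaled to unit centroid size, rotated
#' by least squares onto the current consensus, and the consensus (mean
#' shape, itself re-standardized) is updated until the summed squared
#' deviation from the consensus changes by less than `tol`. Reflections are
#' never solved for — right wings must be mirrored upstream with
#' [mirror_wings()].
#'
#' With `slide_semilandmarks = TRUE` the curve points are slid along their
#' local tangents against the consensus in each iteration, minimizing
#' either the bending energy of the thin-plate-spline deformation from the
#' consensus (`criterion = "bending"`, the default of the tools this
#' workflow descends from) or the Procrustes distance to the consensus
#' (`criterion = "procrustes"`). Curve tangents are taken along the chain
#' `anchor 4 - points 22:27 - anchor 13` (the fixed landmarks bounding the
#' 2m-cu vein) by default.
#'
#' @param wings A wing landmark tibble with no missing landmarks and at
#'   least two specimens sharing one landmark set.
#' @param slide_semilandmarks Slide curve points during superimposition?
#' @param criterion Sliding criterion, `"bending"` or `"procrustes"`.
#' @param curve_anchors Fixed landmark ids bounding the semilandmark curve.
#' @param tol Convergence tolerance on the change in summed squared
#'   deviation from the consensus (default `1e-10`).
#' @param max_iter Maximum superimposition iterations (default 100); an
#'   error reporting the last consensus change is raised if not converged.
#' @param slide_passes Number of outer sliding passes when
#'   `slide_semilandmarks = TRUE` (default 5); each pass slides against
#'   the converged consensus and re-superimposes.
#' @return An object of class `wing_gpa` with elements `coords`
#'   (`p x 2 x n` aligned array, unit centroid size, centered), `consensus`
#'   (`p x 2`), `centroid_sizes` (tibble from [centroid_size()]),
#'   `specimens`, `landmarks`, `semilandmarks`, `slid`, `criterion`,
#'   `iterations`. Methods: [tidy.wing_gpa()], [glance.wing_gpa()],
#'   [autoplot.wing_gpa()].
#' @export
gpa <- function(wings, slide_semilandmarks = FALSE,
                criterion = c("bending", "procrustes"),
                curve_anchors = c(4L, 13L),
                tol = 1e-10, max_iter = 100L, slide_passes = 5L) {
  check_wing_tbl(wings)
  criterion <- match.arg(criterion)
  if (any(wings$missing %||% FALSE)) {
    abort("gpa requires complete configurations; drop or estimate missing landmarks first")
  }
  sizes <- centroid_size(wings)
  if (length(unique(sizes$unit)) > 1) {
    warn("mixed size units (some specimens lack SCALE); centroid sizes are not comparable across units")
  }
  arr <- wings_to_array(wings)
  p <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 2) abort("gpa needs at least 2 configurations")
  lms <- as.integer(dimnames(arr)[[1]])
  semis <- if ("semilandmark" %in% names(wings)) {
    sort(unique(wings$landmark[wings$semilandmark]))
  } else integer()

  for (i in seq_len(n)) {
    X <- center_config(arr[, , i])
    cs <- sqrt(sum(X^2))
    if (cs < .Machine$double.eps^0.5) {
      abort(sprintf("degenerate configuration (all landmarks coincident): %s",
                    dimnames(arr)[[3]][i]))
    }
    arr[, , i] <- X / cs
  }

  superimpose <- function(arr, consensus) {
    Q_old <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      for (i in seq_len(n)) {
        arr[, , i] <- rotate_config(arr[, , i],
                                    opt_rotation_angle(arr[, , i], consensus))
      }
      consensus <- apply(arr, c(1, 2), mean)
      consensus <- center_config(consensus)
      consensus <- consensus / sqrt(sum(consensus^2))
      Q <- sum(apply(arr, 3, function(X) sum((X - consensus)^2)))
      change <- abs(Q_old - Q)
      if (change < tol) break
      if (it >= max_iter) {
        abort(sprintf("gpa did not converge in %d iterations (last change in consensus sum-of-squares: %.3e)",
                      max_iter, change))
      }
      Q_old <- Q
    }
    list(arr = arr, consensus = consensus, iterations = it)
  }

  consensus <- arr[, , 1]
  res <- superimpose(arr, consensus)
  iter <- res$iterations
  if (slide_semilandmarks && length(semis)) {
    # outer sliding passes: slide against the converged consensus, then
    # re-standardize and re-superimpose; a few passes suffice because each
    # pass solves its sliding criterion exactly for the current consensus
    for (s in seq_len(slide_passes)) {
      arr <- slide_all(res$arr, res$consensus, lms, semis, curve_anchors, criterion)
      for (i in seq_len(n)) {
        X <- center_config(arr[, , i])
        arr[, , i] <- X / sqrt(sum(X^2))
      }
      res <- superimpose(arr, res$consensus)
      iter <- iter + res$iterations
    }
  }
  arr <- res$arr
  consensus <- res$consensus

  # canonical orientation: principal axes of the consensus, with a
  # deterministic 180-degree convention, so output does not depend on
  # which specimen seeded the initial consensus (rotation only, det +1)
  V <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 2] <- -V[, 2]
  C2 <- consensus %*% V
  if (C2[which.max(abs(C2[, 1])), 1] < 0) {
    V <- -V
    C2 <- -C2
  }
  dimnames(C2) <- dimnames(res$consensus)
  consensus <- C2
  for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% V
  structure(list(
    coords = arr,
    consensus = consensus,
    centroid_sizes = sizes[match(dimnames(arr)[[3]], sizes$specimen), ],
    specimens = dimnames(arr)[[3]],
    landmarks = lms,
    semilandmarks = semis,
    slid = slide_semilandmarks && length(semis) > 0,
    criterion = if (slide_semilandmarks) criterion else NA_character_,
    iterations = iter
  ), class = "wing_gpa")
}

# one sliding pass over all specimens
slide_all <- function(arr, consensus, lms, semis, anchors, criterion) {
  chain_ids <- c(anchors[1], semis, anchors[2])
  chain <- match(chain_ids, lms)
  if (anyNA(chain)) {
    warn("curve anchors or semilandmarks absent from landmark set; sliding skipped")
    return(arr)
  }
  semi_idx <- match(semis, lms)
  Be <- if (criterion == "bending") bending_energy_matrix(consensus) else NULL
  for (i in seq_len(dim(arr)[3])) {
    arr[, , i] <- slide_one(arr[, , i], consensus, chain, semi_idx, criterion, Be)
  }
  arr
}

slide_one <- function(X, consensus, chain, semi_idx, criterion, Be) {
  k <- length(semi_idx)
  tang <- matrix(0, k, 2)
  ok <- rep(TRUE, k)
  for (j in seq_len(k)) {
    pos <- which(chain == semi_idx[j])
    prev <- X[chain[pos - 1L], ]
    nxt <- X[chain[pos + 1L], ]
    t_ <- nxt - prev
    nrm <- sqrt(sum(t_^2))
    if (nrm < .Machine$double.eps^0.5) {
      warn("degenerate tangent (coincident curve neighbours); semilandmark held fixed")
      ok[j] <- FALSE
    } else {
      tang[j, ] <- t_ / nrm
    }
  }
  if (!any(ok)) return(X)
  if (criterion == "procrustes") {
    for (j in which(ok)) {
      d <- consensus[semi_idx[j], ] - X[semi_idx[j], ]
      X[semi_idx[j], ] <- X[semi_idx[j], ] + sum(d * tang[j, ]) * tang[j, ]
    }
  } else {
    # minimize (y + U t - c)' (Be x I2) (y + U t - c) over slide amounts t
    p <- nrow(X)
    use <- which(ok)
    U <- matrix(0, 2 * p, length(use))
    for (jj in seq_along(use)) {
      j <- use[jj]
      r <- semi_idx[j]
      U[2 * r - 1L, jj] <- tang[j, 1]
      U[2 * r, jj] <- tang[j, 2]
    }
    K <- kronecker(Be, diag(2))
    yv <- as.vector(t(X))        # x1,y1,x2,y2,...
    cv <- as.vector(t(consensus))
    A <- crossprod(U, K %*% U)
    b <- -crossprod(U, K %*% (yv - cv))
    t_hat <- tryCatch(solve(A, b), error = function(e) rep(0, ncol(U)))
    yv <- yv + U %*% t_hat
    X <- matrix(yv, ncol = 2, byrow = TRUE, dimnames = dimnames(X))
  }
  X
}

# thin-plate spline kernel and bending-energy matrix of a 2D configuration
tps_kernel <- function(r2) ifelse(r2 <= 0, 0, r2 * log(r2))

bending_energy_matrix <- function(P) {
  p <- nrow(P)
  D2 <- as.matrix(stats::dist(P))^2
  K <- tps_kernel(D2)
  Q <- cbind(1, P)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Linv <- tryCatch(solve(L), error = function(e) pseudo_inverse(L))
  Linv[seq_len(p), seq_len(p)]
}

# small pseudo-inverse so degenerate (e.g. collinear) references fail softly
pseudo_inverse <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Full Procrustes distance between two configurations
#'
#' The minimum root-summed-squared difference between two landmark
#' configurations over translation, scaling and rotation (reflections are
#' never matched). Computed in closed form via the complex-plane
#' representation: with both configurations centered and scaled to unit
#' centroid size, the full Procrustes distance is `sqrt(1 - rho^2)` where
#' `rho` is the modulus of their Hermitian inner product.
#'
#' @param a,b Landmark matrices (`p x 2`), or single-specimen wing tibbles.
#' @return A nonnegative number; 0 iff the shapes are identical up to a
#'   similarity transform.
#' @export
procrustes_distance <- function(a, b) {
  a <- as_config_matrix(a)
  b <- as_config_matrix(b)
  if (nrow(a) != nrow(b)) abort("configurations must share landmark count")
  za <- complex(real = a[, 1], imaginary = a[, 2])
  zb <- complex(real = b[, 1], imaginary = b[, 2])
  za <- za - mean(za); zb <- zb - mean(zb)
  na <- sqrt(sum(Mod(za)^2)); nb <- sqrt(sum(Mod(zb)^2))
  if (na < .Machine$double.eps^0.5 || nb < .Machine$double.eps^0.5) {
    abort("degenerate configuration: all landmarks coincident")
  }
  za <- za / na; zb <- zb / nb
  rho <- Mod(sum(Conj(za) * zb))
  sqrt(max(0, 1 - rho^2))
}

as_config_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  check_wing_tbl(x)
  if (length(unique(x$specimen)) != 1) {
    abort("expected a single-specimen configuration")
  }
  x <- x[order(x$landmark), ]
  cbind(x = x$x, y = x$y)
}

#' Pairwise full Procrustes distances
#'
#' @param x A `wing_gpa` fit or a wing landmark tibble.
#' @return A symmetric `n x n` matrix of full Procrustes distances.
#' @export
procrustes_dist_matrix <- function(x) {
  arr <- if (inherits(x, "wing_gpa")) x$coords else wings_to_array(x)
  n <- dim(arr)[3]
  D <- matrix(0, n, n, dimnames = list(dimnames(arr)[[3]], dimnames(arr)[[3]]))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- procrustes_distance(arr[, , i], arr[, , j])
    }
  }
  D
}

#' Mean shape of aligned configurations
#'
#' The per-landmark arithmetic mean of Procrustes-aligned coordinates,
#' optionally restricted to the specimens of one group (the per-subfamily
#' mean shapes of comparative wing plots).
#'
#' @param fit A `wing_gpa` object.
#' @param specimens Optional character vector of specimens to average.
#' @return A tibble with columns `landmark`, `x`, `y`.
#' @export
mean_shape <- function(fit, specimens = NULL) {
  stopifnot(inherits(fit, "wing_gpa"))
  arr <- fit$coords
  if (!is.null(specimens)) {
    keep <- dimnames(arr)[[3]] %in% specimens
    if (!any(keep)) abort("no specimens match the requested subset")
    arr <- arr[, , keep, drop = FALSE]
  }
  m <- apply(arr, c(1, 2), mean)
  tibble::tibble(landmark = fit$landmarks, x = m[, 1], y = m[, 2])
}

#' Estimate missing landmarks by thin-plate-spline interpolation
#'
#' Fits the thin-plate-spline deformation carrying the reference's
#' non-missing landmarks onto the specimen's observed landmarks, then
#' evaluates that deformation at the reference positions of the missing
#' landmarks. The interpolant reproduces observed landmarks exactly and
#' reduces to the affine map when the deformation has zero bending energy.
#' Estimated points are flagged, never silently merged: use this only for
#' joint visualisation, not for classification (there, exclude landmarks
#' instead, to avoid leaking reference-group information).
#'
#' @param wings A single-specimen wing tibble with `missing` flags.
#' @param reference A complete configuration: a `p x 2` matrix, a
#'   single-specimen tibble, or a [mean_shape()] tibble.
#' @return The specimen tibble with missing coordinates filled in and a
#'   logical `estimated` column.
#' @export
estimate_missing <- function(wings, reference) {
  check_wing_tbl(wings)
  if (length(unique(wings$specimen)) != 1) abort("estimate one specimen at a time")
  ref <- if (is.matrix(reference)) reference else {
    r <- reference[order(reference$landmark), ]
    cbind(r$x, r$y)
  }
  w <- wings[order(wings$landmark), ]
  if (nrow(w) != nrow(ref)) abort("specimen and reference must share landmark count")
  miss <- w$missing %||% (is.na(w$x) | is.na(w$y))
  if (!any(miss)) {
    w$estimated <- FALSE
    return(w)
  }
  obs <- which(!miss)
  if (length(obs) < 3) abort("need at least 3 observed landmarks to estimate missing ones")
  src <- ref[obs, , drop = FALSE]
  if (abs(stats::cor(src[, 1], src[, 2])^2 - 1) < 1e-12 ||
      qr(cbind(1, src))$rank < 3) {
    abort("observed landmarks are collinear in the reference; TPS estimation is degenerate")
  }
  dst <- cbind(w$x[obs], w$y[obs])
  warp <- tps_warp(src, dst)
  est <- warp(ref[miss, , drop = FALSE])
  w$x[miss] <- est[, 1]
  w$y[miss] <- est[, 2]
  w$missing <- FALSE
  w$estimated <- miss
  w
}

# exact thin-plate-spline interpolant src -> dst; returns an evaluator
tps_warp <- function(src, dst) {
  p <- nrow(src)
  D2 <- as.matrix(stats::dist(src))^2
  K <- tps_kernel(D2)
  Q <- cbind(1, src)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coefs <- solve(L, rhs)
  W <- coefs[seq_len(p), , drop = FALSE]
  A <- coefs[p + 1:3, , drop = FALSE]
  function(pts) {
    d2 <- outer(rowSums(pts^2), rowSums(src^2), "+") - 2 * pts %*% t(src)
    U <- tps_kernel(pmax(d2, 0))
    cbind(1, pts) %*% A + U %*% W
  }
}

# align one configuration onto a target shape (full Procrustes: center,
# unit-scale, optimal rotation); returns the aligned p x 2 matrix
align_to <- function(X, target) {
  X <- center_config(X)
  cs <- sqrt(sum(X^2))
  if (cs < .Machine$double.eps^0.5) abort("degenerate configuration")
  X <- X / cs
  rotate_config(X, opt_rotation_angle(X, target))
}
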