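#' Principal component analysis of aligned shapes
#'
#' Centered eigen-decomposition of the shape covariance on flattened
#' Procrustes coordinates, axes ordered by decreasing variance.
#'
#' @param fit A `wing_gpa` object.
#' @return An object of class `wing_pca` with `scores` (tibble),
#'   `rotation`, `sdev`, `variance_fraction`, `center`.
#' @export
shape_pca <- function(fit) {
  stopifnot(inherits(fit, "wing_gpa"))
  Y <- flatten_coords(fit$coords)
  if (nrow(Y) < 2) abort("PCA needs at least 2 specimens")
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  keep <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  vf <- pc$sdev[keep]^2 / sum(pc$sdev[keep]^2)
  scores <- tibble::as_tibble(pc$x[, keep, drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(specimen = fit$specimens), scores)
  structure(list(scores = scores,
                 rotation = pc$rotation[, keep, drop = FALSE],
                 sdev = pc$sdev[keep],
                 variance_fraction = vf,
                 center = pc$center,
                 landmarks = fit$landmarks),
            class = "wing_pca")
}

#' Canonical variate analysis of grouped shapes
#'
#' Ordination maximising among-group relative to pooled within-group
#' variance (equivalently linear discriminant axes). Because shape
#' dimension typically exceeds sample size, shapes are first projected
#' onto all principal components with non-negligible variance (an
#' information-lossless rotation), capped so the pooled within-group
#' covariance stays full-rank. In that space the canonical axes solve the
#' generalized eigenproblem of between- versus pooled within-group
#' covariance, scaled so canonical scores have pooled within-group
#' covariance equal to the identity. The number of axes is
#' `min(groups - 1, retained dimensions)`.
#'
#' @param fit A `wing_gpa` object (or an `n x d` matrix of shape data).
#' @param groups Group labels (column name with `data`, named vector, or
#'   one label per specimen); every group needs at least 2 members.
#' @param data Optional metadata tibble.
#' @param retain Number of principal components retained before the CVA
#'   (default: all non-null PCs, at most `n - g`).
#' @return An object of class `wing_cva` with canonical `scores` (tibble),
#'   `axes` (in retained-PC space), `shape_axes` (mapped back to flattened
#'   shape space), `group_means_cv`, `explained_variance_fractions`,
#'   `pooled_within_covariance` (in PC space), the pre-projection
#'   (`center`, `rotation`, `retain`) and `groups`.
#' @export
cva <- function(fit, groups, data = NULL, retain = NULL) {
  Y <- if (inherits(fit, "wing_gpa")) flatten_coords(fit$coords) else as.matrix(fit)
  specimens <- rownames(Y) %||% paste0("spec_", seq_len(nrow(Y)))
  lab <- resolve_groups(specimens, groups, data)
  n <- nrow(Y)
  tab <- table(lab)
  if (length(tab) < 2) abort("CVA needs at least 2 groups")
  if (any(tab < 2)) {
    abort(sprintf("group(s) with fewer than 2 members: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  g <- length(tab)
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  sv <- svd(Yc)
  nz <- sum(sv$d^2 > max(sv$d^2) * 1e-12)
  max_retain <- min(nz, n - g)
  r <- min(retain %||% max_retain, max_retain)
  if (r < 1) abort("no usable shape dimensions after pre-projection")
  rot <- sv$v[, seq_len(r), drop = FALSE]
  Z <- Yc %*% rot

  means <- rowsum(Z, lab) / as.vector(tab[sort(unique(lab))])
  means <- means[order(rownames(means)), , drop = FALSE]
  grand <- colMeans(Z)
  W <- matrix(0, r, r)
  for (gr in rownames(means)) {
    Zg <- Z[lab == gr, , drop = FALSE]
    dev <- sweep(Zg, 2, means[gr, ])
    W <- W + crossprod(dev)
  }
  W <- W / (n - g)
  B <- matrix(0, r, r)
  for (gr in rownames(means)) {
    d <- means[gr, ] - grand
    B <- B + tab[[gr]] * tcrossprod(d)
  }
  B <- B / (g - 1)

  eW <- eigen(W, symmetric = TRUE)
  pos <- eW$values > max(eW$values) * 1e-10
  if (!all(pos)) {
    abort("pooled within-group covariance is singular; reduce `retain`")
  }
  Whalf_inv <- eW$vectors %*% (t(eW$vectors) / sqrt(eW$values))
  M <- Whalf_inv %*% B %*% Whalf_inv
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(g - 1L, r)
  A <- Whalf_inv %*% eM$vectors[, seq_len(n_axes), drop = FALSE]
  colnames(A) <- paste0("CV", seq_len(n_axes))
  lambda <- pmax(eM$values[seq_len(n_axes)], 0)

  S <- sweep(Z, 2, grand) %*% A
  colnames(S) <- colnames(A)
  gm <- sweep(means, 2, grand) %*% A
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(specimen = specimens, group = lab),
                              tibble::as_tibble(S)),
    axes = A,
    shape_axes = rot %*% A,
    group_means_cv = gm,
    explained_variance_fractions = if (sum(lambda) > 0) lambda / sum(lambda) else lambda,
    pooled_within_covariance = W,
    center = ctr,
    rotation = rot,
    retain = r,
    grand_pc = grand,
    groups = sort(unique(lab)),
    group_sizes = tab[sort(unique(lab))],
    n = n
  ), class = "wing_cva")
}

#' Leave-one-out cross-validated classification
#'
#' For each specimen the whole classifier — pre-projection PC basis, group
#' means and pooled within-group covariance — is refitted with that
#' specimen held out, and the specimen is assigned to the group with the
#' highest posterior probability (equal priors). Results are tabulated as
#' a confusion matrix with overall accuracy, per-group accuracy and
#' Cohen's Kappa.
#'
#' @inheritParams cva
#' @param priors `"equal"` (default) or `"proportional"` to group sizes.
#' @return A `confusion_summary` object (see [confusion_summary()]).
#' @export
loo_crossvalidate <- function(fit, groups, data = NULL, retain = NULL,
                              priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  Y <- if (inherits(fit, "wing_gpa")) flatten_coords(fit$coords) else as.matrix(fit)
  specimens <- rownames(Y) %||% paste0("spec_", seq_len(nrow(Y)))
  lab <- resolve_groups(specimens, groups, data)
  n <- nrow(Y)
  assigned <- character(n)
  for (i in seq_len(n)) {
    mod <- cva(Y[-i, , drop = FALSE], lab[-i], retain = retain)
    post <- posterior_from_model(mod, Y[i, , drop = FALSE], priors)
    assigned[i] <- post$group[which.max(post$posterior)]
  }
  lev <- sort(unique(lab))
  counts <- table(factor(lab, lev), factor(assigned, lev))
  confusion_summary(unclass(as.matrix(counts)))
}

# posterior probabilities for new rows in original flattened space
posterior_from_model <- function(model, newY, priors = "equal") {
  Zn <- sweep(newY, 2, model$center) %*% model$rotation
  Sn <- sweep(Zn, 2, model$grand_pc) %*% model$axes
  gm <- model$group_means_cv
  d2 <- t(apply(Sn, 1, function(s) colSums((t(gm) - s)^2)))
  if (nrow(d2) != nrow(Sn)) d2 <- t(d2)
  pr <- if (identical(priors, "proportional")) {
    as.vector(model$group_sizes) / sum(model$group_sizes)
  } else rep(1 / length(model$groups), length(model$groups))
  ll <- sweep(-d2 / 2, 2, log(pr), "+")
  post <- t(apply(ll, 1, function(v) {
    e <- exp(v - max(v)); e / sum(e)
  }))
  if (nrow(post) != nrow(Sn)) post <- t(post)
  tibble::tibble(
    row = rep(seq_len(nrow(Sn)), each = length(model$groups)),
    group = rep(model$groups, times = nrow(Sn)),
    mahalanobis = as.vector(t(sqrt(d2))),
    posterior = as.vector(t(post))
  )
}

#' Build a confusion summary from a count matrix
#'
#' @param counts A square matrix of classification counts, rows = true
#'   group, columns = assigned group.
#' @return An object of class `confusion_summary` with elements `counts`,
#'   `percent` (row percentages), `overall_accuracy` (percent), `kappa`,
#'   `per_group_accuracy`. [tidy.confusion_summary()] gives the long form.
#' @export
confusion_summary <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("confusion matrix must be square")
  if (sum(counts) <= 0) abort("confusion matrix has zero total")
  pct <- sweep(counts, 1, pmax(rowSums(counts), 1), "/") * 100
  structure(list(
    counts = counts,
    percent = pct,
    overall_accuracy = 100 * sum(diag(counts)) / sum(counts),
    kappa = cohens_kappa(counts),
    per_group_accuracy = diag(pct)
  ), class = "confusion_summary")
}

#' Reconstruct classification counts from row percentages
#'
#' Published cross-validated classification tables usually print row
#' percentages; with the per-group sample sizes the integer count matrix
#' is recovered by `round(percent x n / 100)` (each row then sums to its
#' group size whenever the printed percentages are consistent).
#'
#' @param percent Square matrix of row percentages.
#' @param class_sizes Integer vector of true-group sizes (row order).
#' @return An integer count matrix.
#' @export
confusion_from_percent <- function(percent, class_sizes) {
  percent <- as.matrix(percent)
  stopifnot(nrow(percent) == length(class_sizes))
  counts <- round(sweep(percent, 1, class_sizes, "*") / 100)
  storage.mode(counts) <- "integer"
  bad <- rowSums(counts) != class_sizes
  if (any(bad)) {
    warn(sprintf("reconstructed row(s) do not sum to the class size: %s",
                 paste(rownames(percent)[bad] %||% which(bad), collapse = ", ")))
  }
  counts
}

#' Cohen's Kappa for a confusion matrix
#'
#' Chance-corrected agreement between true and assigned groups:
#' `(observed agreement - chance agreement) / (1 - chance agreement)`,
#' where chance agreement is the sum of products of row and column
#' marginal proportions. Ranges from -1 (worse than chance) through 0
#' (chance level) to +1 (perfect agreement).
#'
#' @param counts Square nonnegative count matrix (rows = true groups).
#' @return A number in `[-1, 1]`.
#' @export
cohens_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("confusion matrix must be square")
  N <- sum(counts)
  if (N <= 0) abort("confusion matrix has zero total")
  po <- sum(diag(counts)) / N
  pe <- sum((rowSums(counts) / N) * (colSums(counts) / N))
  if (abs(1 - pe) < .Machine$double.eps) return(1)
  (po - pe) / (1 - pe)
}

#' Classify new specimens with a fitted CVA model
#'
#' Aligns each new configuration into the model's shape space (full
#' Procrustes fit onto the training consensus), projects it through the
#' model's pre-projection and canonical axes, and computes the Mahalanobis
#' distance to every group mean in canonical space. Posterior
#' probabilities are proportional to `prior x exp(-d^2/2)`, normalized to
#' sum to one; priors are equal by default. Ties for the winning group are
#' broken by lexicographic group label, with a message.
#'
#' @param model A `wing_cva` fitted to a `wing_gpa` of training specimens,
#'   together with that fit: pass `consensus` (the training consensus
#'   matrix) or let the helper in [place_fossil()] wire it for you.
#' @param wings A wing tibble of one or more new specimens with exactly
#'   the model's landmark set, or an already-aligned `n x d` matrix.
#' @param consensus The training consensus (`p x 2` matrix) used to align
#'   raw configurations; not needed when `wings` is already a flattened
#'   aligned matrix.
#' @param priors `"equal"` or `"proportional"`.
#' @return A tibble with columns `specimen`, `group`, `mahalanobis`,
#'   `posterior`, `winner` (logical).
#' @export
classify_new <- function(model, wings, consensus = NULL,
                         priors = c("equal", "proportional")) {
  stopifnot(inherits(model, "wing_cva"))
  priors <- match.arg(priors)
  if (is.matrix(wings) && ncol(wings) == length(model$center)) {
    newY <- wings
    ids <- rownames(wings) %||% paste0("new_", seq_len(nrow(wings)))
  } else {
    if (is.null(consensus)) abort("raw configurations need `consensus` for alignment")
    arr <- wings_to_array(wings)
    if (dim(arr)[1] != nrow(consensus)) {
      abort(sprintf("landmark subset mismatch: specimen has %d landmarks, model %d",
                    dim(arr)[1], nrow(consensus)))
    }
    ids <- dimnames(arr)[[3]]
    newY <- t(apply(arr, 3, function(X) as.vector(t(align_to(X, consensus)))))
    if (nrow(newY) != length(ids)) newY <- matrix(newY, nrow = length(ids))
  }
  post <- posterior_from_model(model, newY, priors)
  post$specimen <- ids[post$row]
  post$row <- NULL
  out <- dplyr::group_by(post, .data$specimen)
  out <- dplyr::mutate(out, winner = rank(-.data$posterior, ties.method = "first") == 1L)
  out <- dplyr::ungroup(out)
  ties <- dplyr::summarise(dplyr::group_by(post, .data$specimen),
                           tie = sum(.data$posterior == max(.data$posterior)) > 1)
  if (any(ties$tie)) {
    inform(sprintf("posterior tie broken by lexicographic group order for: %s",
                   paste(ties$specimen[ties$tie], collapse = ", ")))
  }
  dplyr::select(out, "specimen", "group", "mahalanobis", "posterior", "winner")
}

#' Between-group PCA with permutation-tested group distances
#'
#' PCA of the group mean shapes (with all specimens projected onto those
#' axes), used instead of a CVA when groups are too small to estimate a
#' within-group covariance — e.g. tribes with a handful of species, or a
#' single fossil kept as its own group. Euclidean distances between group
#' averages are computed in the full aligned shape space; the p-value for
#' each pairwise distance relabels the specimens of the two groups
#' (preserving sizes) and counts permuted distances at least as large as
#' the observed one, the observed relabelling included. When the two
#' groups are small enough, all label splits are enumerated exhaustively
#' instead of sampled.
#'
#' @inheritParams cva
#' @param held_out Specimens (e.g. a fossil) to treat each as its own
#'   group, labelled by their specimen id.
#' @param n_perm Permutation replicates (default 10000; at least 100).
#' @param seed Integer seed.
#' @return An object of class `wing_bgpca` with `scores` (tibble),
#'   `axes`, `variance_fraction`, `distances` (tibble: group1, group2,
#'   distance, p_value, exhaustive), `n_replicates`.
#' @export
bgpca <- function(fit, groups, data = NULL, held_out = NULL,
                  n_perm = 10000L, seed = 42L) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  Y <- if (inherits(fit, "wing_gpa")) flatten_coords(fit$coords) else as.matrix(fit)
  specimens <- rownames(Y) %||% paste0("spec_", seq_len(nrow(Y)))
  lab <- if (!is.null(held_out)) {
    l <- rep(NA_character_, nrow(Y))
    ho <- specimens %in% held_out
    l[ho] <- specimens[ho]
    l[!ho] <- resolve_groups(specimens[!ho], groups, data)
    l
  } else resolve_groups(specimens, groups, data)
  tab <- table(lab)
  if (any(tab == 0)) abort("empty group")
  gs <- sort(unique(lab))
  if (length(gs) < 2) abort("bgPCA needs at least 2 groups")
  means <- rowsum(Y, lab) / as.vector(tab[gs])
  means <- means[gs, , drop = FALSE]
  mctr <- colMeans(means)
  sv <- svd(sweep(means, 2, mctr))
  n_axes <- min(length(gs) - 1L, sum(sv$d > max(sv$d) * 1e-10))
  axes <- sv$v[, seq_len(n_axes), drop = FALSE]
  colnames(axes) <- paste0("bgPC", seq_len(n_axes))
  scr <- sweep(Y, 2, mctr) %*% axes
  vf <- sv$d[seq_len(n_axes)]^2 / sum(sv$d^2)

  dist_rows <- list()
  with_seed_(seed, {
    for (a in seq_along(gs)) {
      for (b in seq_along(gs)) {
        if (b <= a) next
        ia <- which(lab == gs[a]); ib <- which(lab == gs[b])
        d_obs <- sqrt(sum((colMeans(Y[ia, , drop = FALSE]) -
                           colMeans(Y[ib, , drop = FALSE]))^2))
        idx <- c(ia, ib)
        n1 <- length(ia)
        n_splits <- choose(length(idx), n1)
        if (n_splits <= n_perm) {
          splits <- utils::combn(length(idx), n1)
          d_perm <- apply(splits, 2, function(s) {
            sqrt(sum((colMeans(Y[idx[s], , drop = FALSE]) -
                      colMeans(Y[idx[-s], , drop = FALSE]))^2))
          })
          p <- mean(d_perm >= d_obs - 1e-12)
          exhaustive <- TRUE
          nrep <- n_splits
        } else {
          count <- 1L
          for (r in seq_len(n_perm - 1L)) {
            s <- sample(length(idx), n1)
            d_r <- sqrt(sum((colMeans(Y[idx[s], , drop = FALSE]) -
                             colMeans(Y[idx[-s], , drop = FALSE]))^2))
            if (d_r >= d_obs - 1e-12) count <- count + 1L
          }
          p <- count / n_perm
          exhaustive <- FALSE
          nrep <- n_perm
        }
        dist_rows[[length(dist_rows) + 1L]] <- tibble::tibble(
          group1 = gs[a], group2 = gs[b], distance = d_obs,
          p_value = p, exhaustive = exhaustive, n_replicates = nrep)
      }
    }
  })
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(specimen = specimens, group = lab),
                              tibble::as_tibble(scr)),
    axes = axes,
    variance_fraction = vf,
    group_means = means,
    distances = dplyr::bind_rows(dist_rows),
    n_replicates = n_perm,
    seed = seed
  ), class = "wing_bgpca")
}
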