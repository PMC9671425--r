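#' Tidy aligned coordinates of a GPA fit
#'
#' @param x A `wing_gpa` object.
#' @param ... Unused.
#' @return A tibble with one row per specimen x landmark: `specimen`,
#'   `landmark`, `x`, `y`, `semilandmark`, `centroid_size`.
#' @method tidy wing_gpa
#' @export
tidy.wing_gpa <- function(x, ...) {
  out <- array_to_wings(x$coords, semilandmarks = x$semilandmarks)
  out$centroid_size <- x$centroid_sizes$centroid_size[
    match(out$specimen, x$centroid_sizes$specimen)]
  out[c("specimen", "landmark", "x", "y", "semilandmark", "centroid_size")]
}

#' One-row summary of a GPA fit
#' @param x A `wing_gpa` object.
#' @param ... Unused.
#' @method glance wing_gpa
#' @export
glance.wing_gpa <- function(x, ...) {
  tibble::tibble(n = length(x$specimens),
                 landmarks = length(x$landmarks),
                 semilandmarks = length(x$semilandmarks),
                 slid = x$slid,
                 criterion = x$criterion,
                 iterations = x$iterations)
}

#' @export
print.wing_gpa <- function(x, ...) {
  cat(sprintf("GPA fit: %d specimens, %d landmarks (%d semilandmarks%s), %d iterations\n",
              length(x$specimens), length(x$landmarks), length(x$semilandmarks),
              if (x$slid) sprintf(", slid by %s", x$criterion) else "",
              x$iterations))
  invisible(x)
}

#' Plot aligned landmarks and the consensus shape
#' @param object A `wing_gpa` object.
#' @param ... Unused.
#' @method autoplot wing_gpa
#' @export
autoplot.wing_gpa <- function(object, ...) {
  pts <- tidy(object)
  cons <- tibble::tibble(landmark = object$landmarks,
                         x = object$consensus[, 1], y = object$consensus[, 2])
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_point(data = cons, colour = "red", size = 2) +
    ggplot2::geom_text(data = cons, ggplot2::aes(label = .data$landmark),
                       vjust = -0.8, size = 3, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned landmarks",
                  subtitle = "red: consensus shape")
}

#' Tidy a Procrustes ANOVA table
#' @param x A `procrustes_anova` object.
#' @param ... Unused.
#' @method tidy procrustes_anova
#' @export
tidy.procrustes_anova <- function(x, ...) x$table

#' @method glance procrustes_anova
#' @export
glance.procrustes_anova <- function(x, ...) {
  tibble::tibble(n = x$n, n_perm = x$n_perm, seed = x$seed)
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (residual-randomization permutation)\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 5)
  cat(sprintf("%d permutations, seed %d\n", x$n_perm, x$seed))
  invisible(x)
}

#' Tidy regression scores of a shape-size regression
#' @param x A `shape_regression` object.
#' @param ... Unused.
#' @method tidy shape_regression
#' @export
tidy.shape_regression <- function(x, ...) x$scores

#' @method glance shape_regression
#' @export
glance.shape_regression <- function(x, ...) {
  tibble::tibble(percent_predicted = x$percent_predicted,
                 p_value = x$p_value, pooled = x$pooled,
                 n = nrow(x$scores), n_perm = x$n_perm)
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf("%segression of shape on centroid size: %.1f%% predicted, p = %.4g\n",
              if (x$pooled) "Pooled within-group r" else "R",
              x$percent_predicted, x$p_value))
  invisible(x)
}

#' Plot centroid size against regression score
#' @param object A `shape_regression` object.
#' @param ... Unused.
#' @method autoplot shape_regression
#' @export
autoplot.shape_regression <- function(object, ...) {
  xvar <- if (object$pooled) "centered_size" else "centroid_size"
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[xvar]], .data$regression_score,
                               colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = if (object$pooled) "centroid size (group-centred)" else "centroid size",
                  y = "regression score",
                  title = sprintf("Allometry: %.1f%% of shape predicted by size",
                                  object$percent_predicted))
}

#' Tidy canonical scores
#' @param x A `wing_cva` object.
#' @param ... Unused.
#' @method tidy wing_cva
#' @export
tidy.wing_cva <- function(x, ...) x$scores

#' @method glance wing_cva
#' @export
glance.wing_cva <- function(x, ...) {
  tibble::tibble(n = x$n, groups = length(x$groups),
                 axes = ncol(x$axes), retained_pcs = x$retain,
                 cv1_fraction = x$explained_variance_fractions[1])
}

#' Plot the first two canonical axes
#' @param object A `wing_cva` object.
#' @param ... Unused.
#' @method autoplot wing_cva
#' @export
autoplot.wing_cva <- function(object, ...) {
  vf <- object$explained_variance_fractions
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$CV1, .data$CV2, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::stat_ellipse(level = 0.68, linewidth = 0.3) +
    ggplot2::labs(x = sprintf("CV1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("CV2 (%.1f%%)", 100 * vf[2]),
                  title = "Canonical variate analysis")
}

#' Tidy a confusion summary into long form
#' @param x A `confusion_summary` object.
#' @param ... Unused.
#' @return A tibble with `true`, `assigned`, `n`, `percent`.
#' @method tidy confusion_summary
#' @export
tidy.confusion_summary <- function(x, ...) {
  cn <- colnames(x$counts) %||% as.character(seq_len(ncol(x$counts)))
  rn <- rownames(x$counts) %||% cn
  tibble::tibble(
    true = rep(rn, times = ncol(x$counts)),
    assigned = rep(cn, each = nrow(x$counts)),
    n = as.vector(x$counts),
    percent = as.vector(x$percent)
  )
}

#' @method glance confusion_summary
#' @export
glance.confusion_summary <- function(x, ...) {
  tibble::tibble(n = sum(x$counts),
                 overall_accuracy = x$overall_accuracy,
                 kappa = x$kappa)
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Cross-validated classification (row %):\n")
  print(round(x$percent, 2))
  cat(sprintf("Overall classification accuracy: %.2f%% (Kappa statistic: %.2f)\n",
              x$overall_accuracy, x$kappa))
  invisible(x)
}

#' Tidy PCA scores
#' @param x A `wing_pca` object.
#' @param ... Unused.
#' @method tidy wing_pca
#' @export
tidy.wing_pca <- function(x, ...) x$scores

#' @method glance wing_pca
#' @export
glance.wing_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), axes = length(x$sdev),
                 pc1_fraction = x$variance_fraction[1],
                 pc2_fraction = x$variance_fraction[2] %||% NA_real_)
}

#' Plot the first two principal components
#' @param object A `wing_pca` object.
#' @param groups Optional group labels (named vector or per-specimen).
#' @param ... Unused.
#' @method autoplot wing_pca
#' @export
autoplot.wing_pca <- function(object, groups = NULL, ...) {
  d <- object$scores
  vf <- object$variance_fraction
  if (!is.null(groups)) d$group <- resolve_groups(d$specimen, groups)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2))
  p <- if (!is.null(groups)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else p + ggplot2::geom_point()
  p + ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                    y = sprintf("PC2 (%.1f%%)", 100 * vf[2]),
                    title = "Shape morphospace")
}

#' Tidy between-group PCA distances
#' @param x A `wing_bgpca` object.
#' @param ... Unused.
#' @method tidy wing_bgpca
#' @export
tidy.wing_bgpca <- function(x, ...) x$distances

#' @method glance wing_bgpca
#' @export
glance.wing_bgpca <- function(x, ...) {
  tibble::tibble(groups = nrow(x$group_means),
                 axes = ncol(x$axes),
                 n = nrow(x$scores),
                 n_replicates = x$n_replicates)
}

#' Plot between-group PCA scores
#' @param object A `wing_bgpca` object.
#' @param ... Unused.
#' @method autoplot wing_bgpca
#' @export
autoplot.wing_bgpca <- function(object, ...) {
  vf <- object$variance_fraction
  d <- object$scores
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$bgPC1, .data$bgPC2,
                                       colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("bgPC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("bgPC2 (%.1f%%)", 100 * vf[2]),
                  title = "Between-group PCA")
  p
}
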