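#' Permutation-based Procrustes ANOVA
#'
#' Sequential (type-I) multivariate analysis of variance on flattened
#' Procrustes-aligned coordinates. Terms are fitted in the order given
#' (e.g. `~ csize + group + csize:group`); each term's sum of squares is
#' the drop in residual sum of squares when the term enters, so term SS
#' plus residual SS always equals total SS and the R-squared values sum
#' to one. F statistics are ratios of term to residual mean squares;
#' significance comes from residual-randomization permutation (RRPP): for
#' every term the residuals of the reduced model excluding it (and all
#' later terms) are randomly re-assigned to specimens `n_perm` times, the
#' observed statistic counting as one replicate, and the p-value is the
#' fraction of permuted F values at least as large as the observed one.
#'
#' @param fit A `wing_gpa` object.
#' @param formula Right-hand-side formula over columns of `data`; the
#'   pseudo-variable `csize` refers to the fit's centroid sizes.
#' @param data A metadata tibble with a `specimen` column matching the fit.
#' @param n_perm Number of permutation replicates including the observed
#'   (default 1000; must be at least 10).
#' @param seed Integer seed for the permutations (default 42).
#' @return An object of class `procrustes_anova`; [tidy.procrustes_anova()]
#'   returns the ANOVA table (term, df, SS, MS, R2, F, p, with residual
#'   and total rows) in the conventional column order.
#' @export
procrustes_anova <- function(fit, formula, data = NULL, n_perm = 1000L,
                             seed = 42L) {
  stopifnot(inherits(fit, "wing_gpa"))
  if (n_perm < 10) abort("n_perm must be at least 10")
  Y <- flatten_coords(fit$coords)
  n <- nrow(Y)
  df_model <- build_model_frame(fit, data)
  tl <- attr(stats::terms(formula), "term.labels")
  if (!length(tl)) abort("formula must contain at least one term")
  for (v in all.vars(formula)) {
    if (!v %in% names(df_model)) {
      abort(sprintf("variable '%s' not found in metadata (or 'csize')", v))
    }
    if (is.character(df_model[[v]]) || is.factor(df_model[[v]])) {
      if (length(unique(df_model[[v]])) < 2) {
        abort(sprintf("factor '%s' has a single level", v))
      }
    }
  }

  # incremental model matrices, intercept first
  Xs <- vector("list", length(tl) + 1L)
  Xs[[1]] <- matrix(1, n, 1)
  for (k in seq_along(tl)) {
    f_k <- stats::reformulate(tl[seq_len(k)])
    Xs[[k + 1L]] <- stats::model.matrix(f_k, df_model)
  }
  rss <- function(X, Y) {
    fit_ <- stats::lm.fit(X, Y)
    sum(fit_$residuals^2)
  }
  fits <- lapply(Xs, function(X) stats::lm.fit(X, Y))
  rss_k <- vapply(fits, function(f) sum(f$residuals^2), 0)
  rank_k <- vapply(fits, function(f) f$rank, 0L)
  ss_total <- rss_k[1]
  ss_term <- -diff(rss_k)
  df_term <- diff(rank_k)
  if (any(df_term == 0)) abort("a model term adds no estimable degrees of freedom")
  ss_res <- rss_k[length(rss_k)]
  df_res <- n - rank_k[length(rank_k)]
  ms_term <- ss_term / df_term
  ms_res <- ss_res / df_res
  f_obs <- ms_term / ms_res

  p_val <- with_seed_(seed, {
    vapply(seq_along(tl), function(k) {
      f_null <- fits[[k]]
      fitted_null <- Y - f_null$residuals
      resid_null <- f_null$residuals
      X_full_k <- Xs[[k + 1L]]
      X_last <- Xs[[length(Xs)]]
      count <- 1L
      for (b in seq_len(n_perm - 1L)) {
        Yb <- fitted_null + resid_null[sample.int(n), , drop = FALSE]
        rss_null_b <- rss(Xs[[k]], Yb)
        rss_k_b <- rss(X_full_k, Yb)
        rss_full_b <- rss(X_last, Yb)
        f_b <- ((rss_null_b - rss_k_b) / df_term[k]) /
          (rss_full_b / df_res)
        if (isTRUE(f_b >= f_obs[k])) count <- count + 1L
      }
      count / n_perm
    }, 0)
  })

  tab <- tibble::tibble(
    term = c(tl, "Residuals", "Total"),
    df = c(df_term, df_res, n - 1L),
    SS = c(ss_term, ss_res, ss_total),
    MS = c(ms_term, ms_res, NA_real_),
    R2 = c(ss_term / ss_total, ss_res / ss_total, NA_real_),
    F = c(f_obs, NA_real_, NA_real_),
    p = c(p_val, NA_real_, NA_real_)
  )
  structure(list(table = tab, n = n, n_perm = n_perm, seed = seed,
                 formula = formula),
            class = "procrustes_anova")
}

build_model_frame <- function(fit, data) {
  df <- tibble::tibble(specimen = fit$specimens,
                       csize = fit$centroid_sizes$centroid_size)
  if (!is.null(data)) {
    if (!"specimen" %in% names(data)) abort("`data` must have a 'specimen' column")
    extra <- data[match(fit$specimens, data$specimen),
                  setdiff(names(data), c("specimen", "csize")), drop = FALSE]
    df <- dplyr::bind_cols(df, extra)
  }
  df
}

check_size_units <- function(fit, call = rlang::caller_env()) {
  if (length(unique(fit$centroid_sizes$unit)) > 1) {
    abort("mixed centroid-size units (some specimens lack SCALE); size-dependent analyses need one unit",
          call = call)
  }
}

#' Regression of shape on centroid size (allometry)
#'
#' Multivariate regression of flattened Procrustes coordinates on centroid
#' size. Reports the percentage of total shape variation predicted by size
#' (100 x SS(predicted)/SS(total)), per-specimen regression scores (the
#' projection of each centered shape on the allometric direction), and the
#' predicted configurations at the extremes of the observed size range.
#'
#' With `pooled = TRUE` (pooled within-group regression) both centroid
#' sizes and shapes are centered on their group means before a single
#' common slope is fitted: group mean size is zero within every group, so
#' the among-group component of shape is removed and the slope reflects
#' within-group allometry only. This is the appropriate model when size
#' differs systematically among groups, as it does across wasp subfamilies.
#'
#' Significance is a permutation test on the size vector (sizes permuted
#' within groups when pooled), comparing the predicted percentage.
#'
#' @param fit A `wing_gpa` object whose specimens all carry one size unit.
#' @param pooled Center sizes and shapes within groups first?
#' @param groups Group labels (metadata column name with `data`, named
#'   vector, or one label per specimen); required when `pooled = TRUE`.
#' @param data Optional metadata tibble with a `specimen` column.
#' @param n_perm Permutation replicates including the observed.
#' @param seed Integer seed.
#' @return An object of class `shape_regression` with
#'   `percent_predicted`, `p_value`, `direction` (unit allometric vector in
#'   flattened shape space), `scores` (tibble: specimen, centroid size,
#'   regression score, group), `predicted_extremes` (tibble of the two
#'   predicted configurations at the size-range ends) and `pooled`.
#' @export
shape_size_regression <- function(fit, pooled = FALSE, groups = NULL,
                                  data = NULL, n_perm = 1000L, seed = 42L) {
  stopifnot(inherits(fit, "wing_gpa"))
  check_size_units(fit)
  Y <- flatten_coords(fit$coords)
  n <- nrow(Y)
  x <- fit$centroid_sizes$centroid_size
  if (stats::var(x) < .Machine$double.eps) abort("centroid size has zero variance")
  lab <- if (pooled || !is.null(groups)) {
    resolve_groups(fit$specimens, groups %||%
                     abort("pooled regression needs `groups`"), data)
  } else rep("all", n)
  if (pooled) {
    xc <- x - stats::ave(x, lab)
    Yc <- Y - apply(Y, 2, function(col) stats::ave(col, lab))
  } else {
    xc <- x - mean(x)
    Yc <- sweep(Y, 2, colMeans(Y))
  }
  ss_total <- sum(Yc^2)
  if (ss_total < .Machine$double.eps) {
    b <- rep(0, ncol(Y))
  } else {
    b <- as.vector(crossprod(Yc, xc)) / sum(xc^2)
  }
  pred <- outer(xc, b)
  ss_pred <- sum(pred^2)
  pct <- if (ss_total < .Machine$double.eps) 0 else 100 * ss_pred / ss_total
  bn <- sqrt(sum(b^2))
  dir <- if (bn > 0) b / bn else b
  scores <- as.vector(Yc %*% dir)

  p_value <- with_seed_(seed, {
    count <- 1L
    for (i in seq_len(n_perm - 1L)) {
      xp <- if (pooled) {
        unsplit(lapply(split(xc, lab), sample), lab)
      } else sample(xc)
      bp <- as.vector(crossprod(Yc, xp)) / sum(xp^2)
      if (sum(outer(xp, bp)^2) >= ss_pred) count <- count + 1L
    }
    count / n_perm
  })

  cons_flat <- as.vector(t(fit$consensus))
  ext <- range(xc)
  pred_ext <- lapply(ext, function(e) {
    m <- matrix(cons_flat + e * b, ncol = 2, byrow = TRUE)
    tibble::tibble(landmark = fit$landmarks, x = m[, 1], y = m[, 2])
  })
  predicted_extremes <- dplyr::bind_rows(
    dplyr::mutate(pred_ext[[1]], at = "size_min"),
    dplyr::mutate(pred_ext[[2]], at = "size_max"))

  structure(list(
    percent_predicted = pct,
    p_value = p_value,
    direction = dir,
    slope = b,
    scores = tibble::tibble(specimen = fit$specimens,
                            centroid_size = x,
                            centered_size = xc,
                            regression_score = scores,
                            group = lab),
    predicted_extremes = predicted_extremes,
    pooled = pooled,
    n_perm = n_perm, seed = seed
  ), class = "shape_regression")
}

#' Procrustes variance (disparity) per group
#'
#' The mean squared Procrustes-aligned deviation of a group's members from
#' the group mean shape — the standard morphological-disparity measure.
#' Singleton groups carry no dispersion information and are excluded with
#' a warning.
#'
#' @param fit A `wing_gpa` object.
#' @param groups Group labels (column name with `data`, named vector, or
#'   one label per specimen).
#' @param data Optional metadata tibble.
#' @return A tibble with columns `group`, `n`, `procrustes_variance`.
#' @export
procrustes_variance <- function(fit, groups, data = NULL) {
  stopifnot(inherits(fit, "wing_gpa"))
  lab <- resolve_groups(fit$specimens, groups, data)
  Y <- flatten_coords(fit$coords)
  sizes <- table(lab)
  single <- names(sizes)[sizes < 2]
  if (length(single)) {
    warn(sprintf("singleton group(s) excluded: %s", paste(single, collapse = ", ")))
  }
  keep <- setdiff(names(sizes), single)
  if (!length(keep)) abort("no group with at least 2 members")
  purrr::map_dfr(keep, function(g) {
    Yg <- Y[lab == g, , drop = FALSE]
    dev <- sweep(Yg, 2, colMeans(Yg))
    tibble::tibble(group = g, n = nrow(Yg),
                   procrustes_variance = sum(dev^2) / nrow(Yg))
  })
}

#' Within- and between-group mean Procrustes distances
#'
#' Full Procrustes distances between all specimen pairs, summarised as the
#' mean and standard error per group pair (between) and per group
#' (within), sorted by ascending mean distance.
#'
#' @inheritParams procrustes_variance
#' @return A tibble with columns `group1`, `group2`, `type`
#'   (`"within"`/`"between"`), `n_pairs`, `mean_distance`, `se`.
#' @export
group_distance_summary <- function(fit, groups, data = NULL) {
  stopifnot(inherits(fit, "wing_gpa"))
  lab <- resolve_groups(fit$specimens, groups, data)
  D <- procrustes_dist_matrix(fit)
  gs <- sort(unique(lab))
  rows <- list()
  for (a in seq_along(gs)) {
    for (b in a:length(gs)) {
      ia <- which(lab == gs[a]); ib <- which(lab == gs[b])
      if (a == b) {
        if (length(ia) < 2) next
        prs <- utils::combn(ia, 2)
        d <- D[cbind(prs[1, ], prs[2, ])]
      } else {
        d <- as.vector(D[ia, ib])
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group1 = gs[a], group2 = gs[b],
        type = if (a == b) "within" else "between",
        n_pairs = length(d),
        mean_distance = mean(d),
        se = stats::sd(d) / sqrt(length(d))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$mean_distance)
}
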