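#' @importFrom rlang .data abort warn inform %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Convert a long landmark tibble to a landmark array
#'
#' Internal data-model bridge: user-facing functions take tidy tibbles
#' (one row per specimen x landmark), numerical routines work on a
#' `p x 2 x n` array.
#'
#' @param wings A wing landmark tibble with columns `specimen`, `landmark`,
#'   `x`, `y` (see [read_tps()]).
#' @param apply_scale If `TRUE`, multiply coordinates by the per-specimen
#'   `scale` column where present (converting digitizer units to physical
#'   units); specimens without a scale are left untouched.
#' @return A numeric array of dimension `landmarks x 2 x specimens` with
#'   dimnames, specimens in order of first appearance.
#' @export
wings_to_array <- function(wings, apply_scale = FALSE) {
  check_wing_tbl(wings)
  specimens <- unique(wings$specimen)
  lms <- sort(unique(wings$landmark))
  p <- length(lms)
  n <- length(specimens)
  arr <- array(NA_real_, dim = c(p, 2L, n),
               dimnames = list(lms, c("x", "y"), specimens))
  w <- wings
  if (apply_scale && "scale" %in% names(w)) {
    sc <- ifelse(is.na(w$scale), 1, w$scale)
    w$x <- w$x * sc
    w$y <- w$y * sc
  }
  idx_s <- match(w$specimen, specimens)
  idx_l <- match(w$landmark, lms)
  arr[cbind(idx_l, 1L, idx_s)] <- w$x
  arr[cbind(idx_l, 2L, idx_s)] <- w$y
  counts <- table(wings$specimen)
  if (length(unique(counts)) > 1) {
    bad <- names(counts)[counts != p][1]
    abort(sprintf("specimen '%s' has %d landmarks; expected %d",
                  bad, counts[[bad]], p))
  }
  arr
}

#' Convert a landmark array back to a tidy wing tibble
#'
#' @param arr A `p x 2 x n` landmark array (as from [wings_to_array()]).
#' @param specimens Optional specimen names (defaults to array dimnames).
#' @param semilandmarks Integer ids of semilandmark points, if any.
#' @return A wing landmark tibble.
#' @export
array_to_wings <- function(arr, specimens = NULL, semilandmarks = integer()) {
  stopifnot(length(dim(arr)) == 3, dim(arr)[2] == 2)
  p <- dim(arr)[1]; n <- dim(arr)[3]
  specimens <- specimens %||% dimnames(arr)[[3]] %||% paste0("spec_", seq_len(n))
  lms <- dimnames(arr)[[1]] %||% seq_len(p)
  lms <- as.integer(lms)
  tibble::tibble(
    specimen = rep(specimens, each = p),
    landmark = rep(lms, times = n),
    x = as.vector(arr[, 1, ]),
    y = as.vector(arr[, 2, ]),
    semilandmark = rep(lms %in% semilandmarks, times = n),
    missing = is.na(.data$x) | is.na(.data$y)
  )
}

check_wing_tbl <- function(wings, call = rlang::caller_env()) {
  need <- c("specimen", "landmark", "x", "y")
  miss <- setdiff(need, names(wings))
  if (length(miss)) {
    abort(paste0("wing data must have columns ",
                 paste(need, collapse = ", "),
                 "; missing: ", paste(miss, collapse = ", ")), call = call)
  }
  invisible(wings)
}

# flatten p x 2 x n -> n x 2p (x1, y1, x2, y2, ...)
flatten_coords <- function(arr) {
  p <- dim(arr)[1]; n <- dim(arr)[3]
  out <- matrix(aperm(arr, c(2, 1, 3)), nrow = n, ncol = 2 * p, byrow = TRUE)
  rownames(out) <- dimnames(arr)[[3]]
  out
}

# inverse of flatten_coords
unflatten_coords <- function(mat, landmark_ids = NULL) {
  n <- nrow(mat); p <- ncol(mat) / 2
  arr <- aperm(array(t(mat), dim = c(2, p, n)), c(2, 1, 3))
  dimnames(arr) <- list(landmark_ids %||% seq_len(p), c("x", "y"), rownames(mat))
  arr
}

center_config <- function(X) sweep(X, 2, colMeans(X))

config_centroid_size <- function(X) {
  Xc <- center_config(X)
  sqrt(sum(Xc^2))
}

# match group labels (a two-column specimen/label frame or named vector)
# against specimen ids, in specimen order
resolve_groups <- function(specimens, groups, data = NULL,
                           call = rlang::caller_env()) {
  if (is.character(groups) && length(groups) == 1 && !is.null(data)) {
    if (!groups %in% names(data)) {
      abort(sprintf("column '%s' not found in `data`", groups), call = call)
    }
    lab <- data[[groups]][match(specimens, data$specimen)]
  } else if (!is.null(names(groups))) {
    lab <- unname(groups[specimens])
  } else if (length(groups) == length(specimens)) {
    lab <- groups
  } else {
    abort("`groups` must be a metadata column name, a named vector, or one label per specimen",
          call = call)
  }
  if (anyNA(lab)) {
    abort(sprintf("no group label for specimen(s): %s",
                  paste(utils::head(specimens[is.na(lab)], 5), collapse = ", ")),
          call = call)
  }
  as.character(lab)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
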