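#' Idealized wing landmark template
#'
#' A 27-point idealized ichneumonid fore-wing configuration: 21 fixed
#' landmarks at vein junctions and endpoints plus 6 semilandmarks along a
#' gently outward-bowed curve between the fixed landmarks bounding the
#' 2m-cu cross-vein (points 4 and 13). Only the relative geometry matters;
#' coordinates are in arbitrary wing-length units with the wing about 3.6
#' units long and 1.1 high, and the template is non-degenerate (no
#' coincident points).
#'
#' @return A `27 x 2` matrix of template coordinates, rownames `1:27`.
#' @export
wing_template <- function() {
  fixed <- matrix(c(
    0.00, 0.55,   # 1  wing base
    0.55, 0.95,   # 2  costa / pterostigma base
    1.25, 1.05,   # 3  pterostigma apex
    2.05, 0.72,   # 4  anterior end of 2m-cu (curve anchor)
    2.45, 1.02,   # 5
    2.72, 1.08,   # 6
    3.05, 1.00,   # 7
    2.62, 0.80,   # 8  areolet
    2.92, 0.72,   # 9
    3.55, 0.62,   # 10 wing apex region
    2.48, 0.62,   # 11
    2.28, 0.50,   # 12
    2.02, 0.15,   # 13 posterior end of 2m-cu (curve anchor)
    1.52, 0.62,   # 14
    1.50, 0.32,   # 15
    1.05, 0.55,   # 16
    1.02, 0.28,   # 17
    0.60, 0.42,   # 18
    0.62, 0.18,   # 19
    1.15, 0.02,   # 20
    0.25, 0.25    # 21
  ), ncol = 2, byrow = TRUE)
  a <- fixed[4, ]; b <- fixed[13, ]
  t <- seq_len(6) / 7
  curve <- cbind(a[1] + (b[1] - a[1]) * t + 0.12 * sin(pi * t),
                 a[2] + (b[2] - a[2]) * t)
  out <- rbind(fixed, curve)
  rownames(out) <- as.character(1:27)
  colnames(out) <- c("x", "y")
  out
}

# random direction in flattened shape space, centered per axis so it
# carries no translation, scaled to the requested magnitude
random_shape_offset <- function(p, magnitude) {
  if (magnitude <= 0) return(matrix(0, p, 2))
  d <- matrix(stats::rnorm(2 * p), p, 2)
  d <- sweep(d, 2, colMeans(d))
  d / sqrt(sum(d^2)) * magnitude
}

#' Simulate grouped wing-landmark datasets with known ground truth
#'
#' Generates specimens as `template + group offset + (size - mean size) x
#' allometric vector + isotropic Gaussian landmark noise`, scaled so the
#' centroid size equals the drawn size, then randomly rotated and
#' translated. Group offsets are random shape directions of magnitude
#' `group_effect` (full Procrustes units); the allometric vector is a
#' shared random unit direction whose effect grows by `allometry` shape
#' units per size unit. Sizes are uniform on `size_range` per group.
#' Optional nuisance effects emit duplicated copies of every specimen
#' shifted by a fixed shape offset: a second digitizer, a second imaging
#' medium, and a fossil part/counterpart (the latter with left and right
#' wings, right ones mirrored in the raw coordinates).
#'
#' Defaults mirror the structure of a subfamily-level reference dataset:
#' nine groups of 37 species, physical sizes 2.9-8.1 wing-length units,
#' within-group landmark noise `sd = 0.01` in shape units (giving a
#' per-group Procrustes variance near 0.005) and group separation 0.08.
#'
#' @param n_groups Number of groups.
#' @param n_per_group Specimens per group (scalar or vector).
#' @param group_effect Magnitude of each group's mean-shape offset
#'   (full Procrustes units); 0 makes all groups share the template.
#' @param allometry Slope of the shape-on-size relation (shape units per
#'   size unit); 0 disables allometry.
#' @param allometric_vector Optional `27 x 2` matrix giving the allometric
#'   direction (defaults to a seed-determined random unit direction).
#' @param size_range Centroid-size range, recycled per group.
#' @param noise_sd Isotropic per-landmark Gaussian noise sd (shape units).
#' @param digitizer_offset,medium_offset,part_distortion Magnitudes of the
#'   nuisance shape offsets; 0 (default) emits no duplicates.
#' @param seed Integer seed; a fixed seed gives a byte-identical dataset.
#' @return A list of class `wing_simulation`: `wings` (wing tibble in the
#'   TPS schema, `scale = 1`), `metadata` (specimen, group, size, and any
#'   nuisance labels: subject, digitizer, medium, side, part), `truth`
#'   (template, group offsets, allometric vector and slope, noise sd).
#' @export
simulate_wings <- function(n_groups = 9L, n_per_group = 37L,
                           group_effect = 0.08, allometry = 0,
                           allometric_vector = NULL,
                           size_range = c(2.9, 8.1), noise_sd = 0.01,
                           digitizer_offset = 0, medium_offset = 0,
                           part_distortion = 0, seed = 42L) {
  template <- wing_template()
  p <- nrow(template)
  tpl <- center_config(template)
  tpl <- tpl / sqrt(sum(tpl^2))   # unit centroid size, shape units
  n_per_group <- rep_len(n_per_group, n_groups)

  with_seed_(seed, {
    offsets <- lapply(seq_len(n_groups), function(g)
      random_shape_offset(p, group_effect))
    v <- if (is.null(allometric_vector)) {
      random_shape_offset(p, 1)
    } else {
      av <- sweep(allometric_vector, 2, colMeans(allometric_vector))
      av / sqrt(sum(av^2))
    }
    # nuisance effects are fixed shape offsets shared across the dataset,
    # mirroring a systematic digitizer/medium/preservation bias
    dig_off <- random_shape_offset(p, digitizer_offset)
    med_off <- random_shape_offset(p, medium_offset)
    part_off <- random_shape_offset(p, part_distortion)
    rows <- list(); meta <- list()
    for (g in seq_len(n_groups)) {
      gname <- sprintf("G%02d", g)
      sizes <- stats::runif(n_per_group[g], size_range[1], size_range[2])
      for (i in seq_len(n_per_group[g])) {
        id <- sprintf("%s_s%03d", gname, i)
        mean_size <- mean(size_range)
        base <- tpl + offsets[[g]] + allometry * (sizes[i] - mean_size) * v
        emit <- list(list(id = id, shape = base, digitizer = "D1",
                          medium = "illustration", side = "left", part = "part"))
        if (digitizer_offset > 0) {
          emit[[length(emit) + 1L]] <- list(
            id = paste0(id, "_d2"),
            shape = base + dig_off,
            digitizer = "D2", medium = "illustration",
            side = "left", part = "part")
        }
        if (medium_offset > 0) {
          emit[[length(emit) + 1L]] <- list(
            id = paste0(id, "_photo"),
            shape = base + med_off,
            digitizer = "D1", medium = "photo",
            side = "left", part = "part")
        }
        if (part_distortion > 0) {
          for (side in c("left", "right")) {
            emit[[length(emit) + 1L]] <- list(
              id = paste0(id, "_c_", side),
              shape = base + part_off, digitizer = "D1",
              medium = "photo", side = side, part = "counterpart")
          }
          emit[[length(emit) + 1L]] <- list(
            id = paste0(id, "_m_right"),
            shape = base, digitizer = "D1",
            medium = "photo", side = "right", part = "part")
        }
        for (e in emit) {
          shp <- e$shape + matrix(stats::rnorm(2 * p, sd = noise_sd), p, 2)
          shp <- center_config(shp)
          shp <- shp / sqrt(sum(shp^2)) * sizes[i]
          theta <- stats::runif(1, 0, 2 * pi)
          shp <- rotate_config(shp, theta)
          shp <- sweep(shp, 2, stats::runif(2, -2, 2), "+")
          if (e$side == "right") {
            shp[, 1] <- 2 * mean(shp[, 1]) - shp[, 1]
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            specimen = e$id, landmark = 1:p,
            x = unname(shp[, 1]), y = unname(shp[, 2]),
            semilandmark = (1:p) %in% 22:27,
            curve = ifelse((1:p) %in% 22:27, 1L, NA_integer_),
            missing = FALSE, scale = 1,
            image = NA_character_, side = e$side)
          meta[[length(meta) + 1L]] <- tibble::tibble(
            specimen = e$id, subject = id, group = gname,
            subfamily = gname, size = sizes[i],
            digitizer = e$digitizer, medium = e$medium,
            side = e$side, part = e$part)
        }
      }
    }
    structure(list(
      wings = dplyr::bind_rows(rows),
      metadata = dplyr::bind_rows(meta),
      truth = list(template = tpl, group_offsets = offsets,
                   allometric_vector = v, allometry = allometry,
                   group_effect = group_effect, noise_sd = noise_sd,
                   size_range = size_range, seed = seed)
    ), class = "wing_simulation")
  })
}
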