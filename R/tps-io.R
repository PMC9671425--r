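#' Read a TPS landmark file
#'
#' Parses the tpsDig2 dialect of the TPS format: records start with `LM=<k>`,
#' followed by `k` coordinate lines, optionally `CURVES=<c>` with per-curve
#' `POINTS=<m>` blocks, and trailing `IMAGE=`, `ID=` and `SCALE=` keys.
#' Keys are matched case-insensitively; unknown keys are skipped with a
#' warning (tpsDig2 files vary). Curve points are appended after the fixed
#' landmarks and flagged as semilandmarks. `SCALE` is stored but not applied
#' (see [wings_to_array()] with `apply_scale = TRUE`); a coordinate line
#' reading `NA NA` marks a missing landmark.
#'
#' @param path Path to a TPS file.
#' @return A tibble with one row per specimen x landmark and columns
#'   `specimen`, `landmark` (1-based point index; fixed landmarks first,
#'   then curve points), `x`, `y`, `semilandmark`, `curve` (curve number or
#'   `NA` for fixed points), `missing`, `scale` (`NA` when the record has no
#'   SCALE line), `image`, `side` (`"unknown"`; see [mirror_wings()]).
#'   Record order is preserved.
#' @seealso [write_tps()], [drop_landmarks()], [mirror_wings()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  rec_no <- 0L

  read_coords <- function(k, what, rec_id) {
    out <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > n_lines) {
        abort(sprintf("record %s: expected %d %s coordinate lines, file ended after %d",
                      rec_id, k, what, j - 1L))
      }
      ln <- lines[i]
      if (grepl("^[A-Za-z]+=", ln)) {
        abort(sprintf("record %s: expected %d %s coordinate lines but found key '%s' after %d",
                      rec_id, k, what, sub("=.*", "=", ln), j - 1L))
      }
      toks <- strsplit(ln, "[ \t]+")[[1]]
      toks <- toks[toks != ""]
      if (length(toks) != 2) {
        abort(sprintf("line %d: expected two coordinate values, got '%s'", i, ln))
      }
      if (identical(toupper(toks), c("NA", "NA"))) {
        out[j, ] <- c(NA_real_, NA_real_)
      } else {
        vals <- suppressWarnings(as.numeric(toks))
        if (anyNA(vals)) {
          abort(sprintf("line %d: non-numeric coordinate '%s'", i, ln))
        }
        out[j, ] <- vals
      }
      i <<- i + 1L
    }
    out
  }

  while (i <= n_lines) {
    ln <- lines[i]
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^lm\\s*=", ln, ignore.case = TRUE)) {
      warn(sprintf("line %d: ignoring content outside a record: '%s'", i, ln))
      i <- i + 1L
      next
    }
    rec_no <- rec_no + 1L
    rec_id <- sprintf("#%d", rec_no)
    k_fixed <- suppressWarnings(as.integer(sub("(?i)^lm\\s*=\\s*", "", ln, perl = TRUE)))
    if (is.na(k_fixed) || k_fixed < 0) abort(sprintf("line %d: bad LM= count", i))
    i <- i + 1L
    fixed <- read_coords(k_fixed, "fixed", rec_id)
    curves <- list()
    id <- NULL; image <- NA_character_; scale <- NA_real_
    while (i <= n_lines) {
      ln <- lines[i]
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^lm\\s*=", ln, ignore.case = TRUE)) break
      key <- toupper(sub("\\s*=.*$", "", ln))
      val <- sub("^[^=]*=\\s*", "", ln)
      i <- i + 1L
      if (key == "CURVES") {
        nc <- as.integer(val)
        for (ci in seq_len(nc)) {
          if (i > n_lines || !grepl("^points\\s*=", lines[i], ignore.case = TRUE)) {
            abort(sprintf("record %s: CURVES=%d but POINTS= line %d missing", rec_id, nc, ci))
          }
          m <- as.integer(sub("(?i)^points\\s*=\\s*", "", lines[i], perl = TRUE))
          i <- i + 1L
          curves[[ci]] <- read_coords(m, sprintf("curve %d", ci), rec_id)
        }
      } else if (key == "ID") {
        id <- val
      } else if (key == "IMAGE") {
        image <- val
      } else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale) || scale <= 0) {
          abort(sprintf("record %s: SCALE must be a positive number, got '%s'", rec_id, val))
        }
      } else if (key == "POINTS") {
        abort(sprintf("record %s: POINTS= outside a CURVES block", rec_id))
      } else {
        warn(sprintf("record %s: ignoring unknown key '%s='", rec_id, key))
      }
    }
    coords <- fixed
    curve_no <- rep(NA_integer_, k_fixed)
    for (ci in seq_along(curves)) {
      coords <- rbind(coords, curves[[ci]])
      curve_no <- c(curve_no, rep(ci, nrow(curves[[ci]])))
    }
    recs[[rec_no]] <- list(id = id %||% rec_id, coords = coords,
                           curve = curve_no, k_fixed = k_fixed,
                           image = image, scale = scale)
  }

  if (!length(recs)) {
    return(tibble::tibble(specimen = character(), landmark = integer(),
                          x = double(), y = double(),
                          semilandmark = logical(), curve = integer(),
                          missing = logical(), scale = double(),
                          image = character(), side = character()))
  }
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_dup")
  }
  purrr::map2_dfr(recs, ids, function(r, id) {
    p <- nrow(r$coords)
    tibble::tibble(
      specimen = id,
      landmark = seq_len(p),
      x = r$coords[, 1],
      y = r$coords[, 2],
      semilandmark = !is.na(r$curve),
      curve = r$curve,
      missing = is.na(r$coords[, 1]) | is.na(r$coords[, 2]),
      scale = r$scale,
      image = r$image,
      side = "unknown"
    )
  })
}

#' Write wing landmark data to a TPS file
#'
#' Emits the tpsDig2 dialect read by [read_tps()]: fixed landmarks under
#' `LM=`, semilandmarks as a `CURVES=`/`POINTS=` block, `ID=` always, and
#' `SCALE=` only when present. Coordinates are written with 12 significant
#' digits so a write/read round trip is stable at the emitted precision.
#'
#' @param wings A wing landmark tibble (columns `specimen`, `landmark`, `x`,
#'   `y`; optional `semilandmark`, `scale`, `image`, `missing`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(wings, path) {
  check_wing_tbl(wings)
  specimens <- unique(wings$specimen)
  if (length(specimens)) {
    counts <- table(factor(wings$specimen, levels = specimens))
    if (length(unique(counts)) > 1) {
      abort("all specimens must share the same landmark count to write one TPS file")
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(v) {
    ifelse(is.na(v), "NA", sprintf("%.12g", v))
  }
  for (s in specimens) {
    w <- wings[wings$specimen == s, ]
    w <- w[order(w$landmark), ]
    semi <- if ("semilandmark" %in% names(w)) w$semilandmark else rep(FALSE, nrow(w))
    fixed <- w[!semi, ]
    curvep <- w[semi, ]
    writeLines(sprintf("LM=%d", nrow(fixed)), con)
    writeLines(paste(fmt(fixed$x), fmt(fixed$y)), con)
    if (nrow(curvep)) {
      writeLines("CURVES=1", con)
      writeLines(sprintf("POINTS=%d", nrow(curvep)), con)
      writeLines(paste(fmt(curvep$x), fmt(curvep$y)), con)
    }
    if ("image" %in% names(w) && !is.na(w$image[1])) {
      writeLines(sprintf("IMAGE=%s", w$image[1]), con)
    }
    writeLines(sprintf("ID=%s", s), con)
    if ("scale" %in% names(w) && !is.na(w$scale[1])) {
      writeLines(sprintf("SCALE=%.12g", w$scale[1]), con)
    }
  }
  invisible(path)
}

#' Mirror wing configurations about the vertical axis
#'
#' Wings are digitized in a planar standard orientation, so a right wing is
#' turned into its left-wing equivalent by reflecting x-coordinates about
#' the configuration centroid's vertical axis. Mirroring is an isometry:
#' centroid size and all shape relations are preserved. Superimposition
#' never solves for reflections, so right wings must be mirrored before any
#' joint analysis with left wings.
#'
#' @param wings A wing landmark tibble.
#' @param specimens Specimens to mirror (default all).
#' @return The tibble with mirrored x-coordinates and the `side` label
#'   flipped (`left` <-> `right`; `unknown` stays).
#' @export
mirror_wings <- function(wings, specimens = NULL) {
  check_wing_tbl(wings)
  specimens <- specimens %||% unique(wings$specimen)
  sel <- wings$specimen %in% specimens
  cx <- stats::ave(wings$x, wings$specimen, FUN = function(v) mean(v, na.rm = TRUE))
  wings$x[sel] <- 2 * cx[sel] - wings$x[sel]
  if (!"side" %in% names(wings)) wings$side <- "unknown"
  flip <- c(left = "right", right = "left", unknown = "unknown")
  wings$side[sel] <- unname(flip[wings$side[sel]])
  wings
}

#' Drop landmarks from every specimen
#'
#' Landmark exclusion for fossil comparisons: the listed point indices are
#' removed uniformly from every specimen so all configurations stay
#' comparable. Because the semilandmarks jointly describe one curve (the
#' 2m-cu vein), excluding any semilandmark removes the whole curve.
#'
#' @param wings A wing landmark tibble.
#' @param drop Integer landmark indices to remove; `integer(0)` is a no-op.
#' @param semilandmark_ids Ids forming the semilandmark curve
#'   (default `22:27`).
#' @return The tibble restricted to the retained landmarks (original
#'   landmark ids are kept, not renumbered).
#' @export
drop_landmarks <- function(wings, drop, semilandmark_ids = 22:27) {
  check_wing_tbl(wings)
  drop <- as.integer(drop)
  if (!length(drop)) return(wings)
  present <- unique(wings$landmark)
  if (!all(drop %in% present)) {
    abort(sprintf("landmark index out of range: %s",
                  paste(setdiff(drop, present), collapse = ", ")))
  }
  if (any(drop %in% semilandmark_ids)) {
    drop <- union(drop, intersect(semilandmark_ids, present))
  }
  keep <- setdiff(present, drop)
  if (!length(keep)) abort("cannot drop all landmarks")
  wings[wings$landmark %in% keep, ]
}

#' Read a specimen label sidecar table
#'
#' Group membership (subfamily, tribe, genus), wing side and provenance are
#' carried in a delimited sidecar table keyed by `specimen`, matching the
#' schema emitted by [simulate_wings()].
#'
#' @param path Path to a tab- or comma-delimited text file with a header;
#'   must contain a `specimen` column.
#' @return A tibble of specimen metadata.
#' @export
read_wing_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  out <- tibble::as_tibble(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE))
  if (!"specimen" %in% names(out)) abort("label table must have a 'specimen' column")
  out
}
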