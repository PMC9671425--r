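#' Configuration for one fossil placement
#'
#' Bundles the taxonomic and numerical choices of a fossil-placement run:
#' the candidate subfamilies (pre-selected from body characters), the
#' landmark indices excluded because they were placed with uncertainty in
#' the fossil, the decision thresholds, and the refinement rank. All three
#' thresholds are strict inequalities and must hold jointly for the
#' refinement to be restricted to the winning subfamily.
#'
#' @param fossil_id Specimen id of the fossil.
#' @param candidates Character vector of at least two candidate group
#'   labels.
#' @param excluded_landmarks Integer landmark indices excluded from fossil
#'   and reference alike (excluding any semilandmark removes the whole
#'   curve).
#' @param min_accuracy Reference-CVA overall accuracy threshold in percent
#'   (default 80).
#' @param min_kappa Cohen's Kappa threshold (default 0.7).
#' @param min_posterior Posterior-probability threshold (default 0.9).
#' @param refinement_rank Metadata column used for the refinement bgPCA
#'   (default `"tribe"`).
#' @param n_perm Permutation replicates for the bgPCA (default 10000).
#' @param seed Integer seed (default 42).
#' @return An object of class `placement_config`.
#' @export
placement_config <- function(fossil_id, candidates, excluded_landmarks = integer(),
                             min_accuracy = 80, min_kappa = 0.7,
                             min_posterior = 0.9, refinement_rank = "tribe",
                             n_perm = 10000L, seed = 42L) {
  if (length(candidates) < 2) abort("degenerate classification: need at least 2 candidate groups")
  stopifnot(min_accuracy >= 0, min_accuracy <= 100,
            min_kappa >= -1, min_kappa <= 1,
            min_posterior >= 0, min_posterior <= 1)
  structure(list(fossil_id = fossil_id, candidates = candidates,
                 excluded_landmarks = as.integer(excluded_landmarks),
                 min_accuracy = min_accuracy, min_kappa = min_kappa,
                 min_posterior = min_posterior,
                 refinement_rank = refinement_rank,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "placement_config")
}

#' Place a fossil specimen into the extant classification
#'
#' The end-to-end decision procedure for one fossil: (1) drop the
#' config's excluded landmarks from reference and fossil alike and re-run
#' GPA on the reduced landmark set; (2) leave-one-out cross-validated CVA
#' of the candidate groups, never including the fossil; (3) posterior
#' assignment of the fossil to the candidate groups; (4) threshold
#' evaluation — accuracy > `min_accuracy`, Kappa > `min_kappa` and winning
#' posterior > `min_posterior` must all hold strictly; (5) refinement
#' bgPCA at `refinement_rank` within the winning group if the thresholds
#' are met, otherwise across the tribes of all candidate groups, with the
#' fossil kept as its own group.
#'
#' @param reference Wing tibble of reference specimens (complete
#'   landmark sets).
#' @param fossil Wing tibble of the fossil specimen.
#' @param config A [placement_config()].
#' @param data Metadata tibble with `specimen`, the candidate-group column
#'   (default `subfamily`) and the refinement-rank column.
#' @param group_col Metadata column holding the candidate group labels.
#' @return An object of class `placement_report`: `candidate_cva`
#'   (a `confusion_summary`), `assignment` (posterior tibble),
#'   `thresholds` (per-criterion tibble), `thresholds_met`, `winner`,
#'   `refinement` (a `wing_bgpca`), `refinement_scope`, `narrative_flags`,
#'   `training_hash`, `config`.
#' @export
place_fossil <- function(reference, fossil, config, data,
                         group_col = "subfamily") {
  stopifnot(inherits(config, "placement_config"))
  check_wing_tbl(reference); check_wing_tbl(fossil)
  if (!group_col %in% names(data)) {
    abort(sprintf("metadata lacks the '%s' column", group_col))
  }
  fossil_ids <- unique(fossil$specimen)
  if (any(fossil_ids %in% unique(reference$specimen))) {
    abort("fossil specimen id collides with a reference specimen")
  }
  # fossil landmarks flagged missing must be covered by the exclusions
  if ("missing" %in% names(fossil)) {
    uncovered <- unique(fossil$landmark[fossil$missing &
                                        !fossil$landmark %in% config$excluded_landmarks])
    if (length(uncovered)) {
      abort(sprintf("fossil has missing landmark(s) not excluded by the config: %s",
                    paste(uncovered, collapse = ", ")))
    }
  }
  keep_specs <- data$specimen[data[[group_col]] %in% config$candidates]
  ref <- reference[reference$specimen %in% keep_specs, ]
  if (!length(unique(ref$specimen))) abort("no reference specimens in the candidate groups")
  ref <- drop_landmarks(ref, config$excluded_landmarks)
  fos <- drop_landmarks(fossil, config$excluded_landmarks)
  if (!setequal(unique(fos$landmark), unique(ref$landmark))) {
    abort("fossil landmark set inconsistent with config: reference and fossil differ after exclusion")
  }

  fit_ref <- gpa(ref)
  training_hash <- paste(sort(fit_ref$specimens), collapse = "|")
  stopifnot(!any(fossil_ids %in% fit_ref$specimens))
  lab <- resolve_groups(fit_ref$specimens, group_col, data)
  cand_cva <- loo_crossvalidate(fit_ref, lab)
  model <- cva(fit_ref, lab)
  assignment <- classify_new(model, fos, consensus = fit_ref$consensus)
  win_row <- assignment[assignment$winner, ]
  winner <- win_row$group[1]
  top_post <- win_row$posterior[1]

  thresholds <- tibble::tibble(
    criterion = c("accuracy", "kappa", "posterior"),
    value = c(cand_cva$overall_accuracy, cand_cva$kappa, top_post),
    threshold = c(config$min_accuracy, config$min_kappa, config$min_posterior),
    met = c(cand_cva$overall_accuracy > config$min_accuracy,
            cand_cva$kappa > config$min_kappa,
            top_post > config$min_posterior)
  )
  thresholds_met <- all(thresholds$met)

  flags <- character()
  if (length(fossil_ids) > 1) {
    flags <- c(flags, "multiple fossil specimens placed with one config")
  }
  refine_groups <- if (thresholds_met) winner else config$candidates
  if (!thresholds_met) {
    flags <- c(flags,
               sprintf("thresholds not met - bgPCA run on all candidate groups' %ss",
                       config$refinement_rank))
  }
  refinement <- NULL
  if (config$refinement_rank %in% names(data)) {
    ref_specs <- data$specimen[data[[group_col]] %in% refine_groups &
                               !is.na(data[[config$refinement_rank]])]
    sub <- reference[reference$specimen %in% ref_specs, ]
    sub <- drop_landmarks(sub, config$excluded_landmarks)
    joint <- dplyr::bind_rows(sub[intersect(names(sub), names(fos))],
                              fos[intersect(names(sub), names(fos))])
    fit_joint <- gpa(joint)
    refinement <- bgpca(fit_joint, config$refinement_rank, data = data,
                        held_out = fossil_ids,
                        n_perm = config$n_perm, seed = config$seed)
  } else {
    flags <- c(flags, sprintf("no '%s' column in metadata - refinement skipped",
                              config$refinement_rank))
  }

  structure(list(
    candidate_cva = cand_cva,
    assignment = assignment,
    thresholds = thresholds,
    thresholds_met = thresholds_met,
    winner = winner,
    refinement = refinement,
    refinement_scope = refine_groups,
    narrative_flags = flags,
    training_hash = training_hash,
    config = config
  ), class = "placement_report")
}

#' Data-quality assessment: landmark placement by different digitizers
#'
#' Procrustes ANOVA of shape on specimen identity and digitizer for a
#' dataset in which the same wings were digitized more than once. A
#' digitizer effect near zero (both in R-squared and significance) shows
#' landmark placement is operator-consistent.
#'
#' @param wings Wing tibble containing repeated digitizations.
#' @param data Metadata with `specimen`, `subject` (the physical wing) and
#'   `digitizer` columns.
#' @param n_perm,seed Permutation settings.
#' @return A `procrustes_anova` for `~ subject + digitizer`.
#' @export
assess_observer_bias <- function(wings, data, n_perm = 1000L, seed = 42L) {
  need <- c("subject", "digitizer")
  if (!all(need %in% names(data))) {
    abort("metadata needs 'subject' and 'digitizer' columns")
  }
  if (!any(duplicated(data$subject))) {
    abort("no duplicated digitizations: every subject appears once")
  }
  fit <- gpa(wings)
  procrustes_anova(fit, ~ subject + digitizer, data = data,
                   n_perm = n_perm, seed = seed)
}

#' Data-quality assessment: photographs versus standardised illustrations
#'
#' Procrustes ANOVA of shape on imaging medium and species for wings
#' captured both as photographs and as standardised drawings, plus a PCA
#' of the aligned shapes for visual audit.
#'
#' @param wings Wing tibble with both media per species.
#' @param data Metadata with `specimen`, `medium` and `species` columns.
#' @param n_perm,seed Permutation settings.
#' @return A list with `anova` (a `procrustes_anova` for
#'   `~ medium + species`) and `pca` (a `wing_pca`).
#' @export
assess_media_bias <- function(wings, data, n_perm = 1000L, seed = 42L) {
  need <- c("medium", "species")
  if (!all(need %in% names(data))) {
    abort("metadata needs 'medium' and 'species' columns")
  }
  fit <- gpa(wings)
  list(
    anova = procrustes_anova(fit, ~ medium + species, data = data,
                             n_perm = n_perm, seed = seed),
    pca = shape_pca(fit)
  )
}

#' Data-quality assessment: fossilisation artefacts
#'
#' Procrustes ANOVA of fossil wing shape on specimen, wing side (left or
#' mirrored right) and fossil part (part or counterpart). Landmarks placed
#' with uncertainty in any fossil are excluded first (default 1, 2, 18,
#' 19, matching the points that are uncertain in at least one compression
#' fossil).
#'
#' @param wings Wing tibble of fossil wings (right wings already
#'   mirrored).
#' @param data Metadata with `specimen`, `subject`, `side` and `part`
#'   columns.
#' @param exclude Landmark indices removed before the analysis.
#' @param n_perm,seed Permutation settings.
#' @return A `procrustes_anova` for `~ subject + side + part`.
#' @export
assess_fossil_artefacts <- function(wings, data, exclude = c(1L, 2L, 18L, 19L),
                                    n_perm = 1000L, seed = 42L) {
  need <- c("subject", "side", "part")
  if (!all(need %in% names(data))) {
    abort("metadata needs 'subject', 'side' and 'part' columns")
  }
  w <- drop_landmarks(wings, intersect(exclude, unique(wings$landmark)))
  fit <- gpa(w)
  procrustes_anova(fit, ~ subject + side + part, data = data,
                   n_perm = n_perm, seed = seed)
}

#' @export
print.placement_report <- function(x, ...) {
  cat(sprintf("Fossil placement report: %s\n", x$config$fossil_id))
  cat(sprintf("  Candidates: %s\n", paste(x$config$candidates, collapse = ", ")))
  cat(sprintf("  Excluded landmarks: %s\n",
              if (length(x$config$excluded_landmarks))
                paste(x$config$excluded_landmarks, collapse = ", ") else "none"))
  cat(sprintf("  Reference CVA: accuracy %.1f%%, kappa %.3f\n",
              x$candidate_cva$overall_accuracy, x$candidate_cva$kappa))
  win <- x$assignment[x$assignment$winner, ]
  cat(sprintf("  Assignment: %s (posterior %.3f)\n", win$group[1], win$posterior[1]))
  cat(sprintf("  Thresholds met: %s\n", x$thresholds_met))
  if (!is.null(x$refinement)) {
    cat(sprintf("  Refinement (%s) over: %s\n", x$config$refinement_rank,
                paste(x$refinement_scope, collapse = ", ")))
  }
  for (f in x$narrative_flags) cat(sprintf("  note: %s\n", f))
  invisible(x)
}
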