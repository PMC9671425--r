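#' Published subfamily classification tables
#'
#' Row-percentage cross-validated classification tables reported for the
#' nine- and seven-subfamily reference analyses of ichneumonid fore
#' wings, shipped with the package together with the per-subfamily sample
#' sizes. With [confusion_from_percent()] and [confusion_summary()] the
#' integer count matrices, overall accuracies and Kappa statistics are
#' recovered from these percentages alone.
#'
#' @param which `"nine"` (default) or `"seven"` subfamilies.
#' @return A list with `percent` (named square matrix of row
#'   percentages) and `class_sizes` (named integer vector).
#' @export
published_classification <- function(which = c("nine", "seven")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("subfamily_classification_%s.csv",
                              if (which == "nine") "9" else "7"),
                      package = "wingmorph", mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE)
  pct <- as.matrix(raw[, -(1:2)])
  rownames(pct) <- raw$true
  sizes <- stats::setNames(as.integer(raw$n), raw$true)
  list(percent = pct, class_sizes = sizes)
}

#' Re-run the reference-dataset analyses from deposited TPS files
#'
#' Executes the full subfamily-informativeness workflow on the deposited
#' reference landmark data (333 extant species, 21 fixed landmarks + 6
#' semilandmarks): GPA on the fixed landmarks, Procrustes ANOVA of shape
#' on centroid size, subfamily and their interaction, raw and pooled
#' within-group shape-size regression, per-subfamily Procrustes variances,
#' pairwise group distance summary, and the nine-subfamily leave-one-out
#' CVA on all 27 landmarks. The deposited files are not redistributed
#' with the package; point `tps_path`/`labels_path` at local copies.
#'
#' @param tps_path TPS file of the extant reference wings.
#' @param labels_path Sidecar label table (see [read_wing_labels()]) with
#'   a `subfamily` column.
#' @param n_perm,seed Permutation settings for the ANOVA and regressions.
#' @return A list: `anova` (`procrustes_anova`), `regression_raw`,
#'   `regression_pooled` (`shape_regression`), `disparity` (tibble),
#'   `distance_summary` (tibble), `loo` (`confusion_summary`, all 27
#'   landmarks).
#' @export
reproduce_reference_analysis <- function(tps_path, labels_path,
                                         n_perm = 1000L, seed = 42L) {
  wings <- read_tps(tps_path)
  labels <- read_wing_labels(labels_path)
  fixed <- drop_landmarks(wings, 22L)   # drops the whole semilandmark curve
  fit_fixed <- gpa(fixed)
  anova <- procrustes_anova(fit_fixed, ~ csize + subfamily + csize:subfamily,
                            data = labels, n_perm = n_perm, seed = seed)
  reg_raw <- shape_size_regression(fit_fixed, n_perm = n_perm, seed = seed)
  reg_pooled <- shape_size_regression(fit_fixed, pooled = TRUE,
                                      groups = "subfamily", data = labels,
                                      n_perm = n_perm, seed = seed)
  disparity <- procrustes_variance(fit_fixed, "subfamily", data = labels)
  dists <- group_distance_summary(fit_fixed, "subfamily", data = labels)
  fit_all <- gpa(wings, slide_semilandmarks = TRUE)
  loo <- loo_crossvalidate(fit_all, "subfamily", data = labels)
  list(anova = anova, regression_raw = reg_raw,
       regression_pooled = reg_pooled, disparity = disparity,
       distance_summary = dists, loo = loo)
}
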