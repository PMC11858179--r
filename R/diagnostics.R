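## Diagnostic-fragment discovery from a fitted PCA: each analyte group has a
## direction in component (score) space; a variable whose loading vector
## points the same way is specific to that group, and its loading magnitude
## tracks the fragment's abundance (the data are centred, never
## variance-scaled). Aligned loading vectors (pairwise cosine near 1) flag
## consecutive-fragmentation series.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

#' Rank diagnostic variables per analyte group
#'
#' For each group, the mean score vector of its samples (over the chosen
#' components) defines the group direction. Each variable's specificity is
#' the cosine between its loading vector and that direction (in [-1, 1]);
#' variables are ranked by specificity x loading magnitude, with ties broken
#' by ascending m/z so rankings are stable. The pairwise cosine matrix
#' between variable loading vectors is returned alongside: proportional
#' intensity profiles give cosines near 1.
#'
#' @param model A `nipals_pca` fit with at least 2 components.
#' @param groups Group label per sample (length = number of samples), e.g.
#'   the peptide identity; at least 2 distinct groups, none empty.
#' @param components Components spanning the diagnostic plane (default all
#'   fitted).
#' @return A `diagnostic_report`: list with `ranking` (tibble: `group`,
#'   `mz`, `variable`, `loading_magnitude`, `specificity`, `score`, `rank`),
#'   `similarity` (variables x variables cosine matrix) and
#'   `group_directions`.
#' @export
rank_diagnostics <- function(model, groups,
                             components = seq_len(model$n_components)) {
  stopifnot(inherits(model, "nipals_pca"))
  if (model$n_components < 2L) {
    stop("diagnostic ranking needs a model with >= 2 components", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(model$scores)) {
    stop("one group label per sample is required", call. = FALSE)
  }
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(factor(groups, lev)) == 0L)) {
    stop("every group needs at least one sample", call. = FALSE)
  }
  S <- model$scores[, components, drop = FALSE]
  L <- model$loadings[, components, drop = FALSE]
  mzs <- model$variable_mzs
  if (is.null(mzs)) mzs <- rep(NA_real_, nrow(L))
  dirs <- t(vapply(lev, function(g) {
    .unit(colMeans(S[groups == g, , drop = FALSE]))
  }, numeric(ncol(S))))
  rownames(dirs) <- lev
  mag <- sqrt(rowSums(L^2))
  Lu <- L / ifelse(mag > 0, mag, 1)
  rank_tbl <- dplyr::bind_rows(lapply(lev, function(g) {
    spec <- drop(Lu %*% dirs[g, ])
    score <- spec * mag
    ord <- order(-score, mzs)
    tibble::tibble(group = g, variable = ord, mz = mzs[ord],
                   loading_magnitude = mag[ord], specificity = spec[ord],
                   score = score[ord], rank = seq_along(ord))
  }))
  sim <- tcrossprod(Lu)
  dimnames(sim) <- list(format(mzs, trim = TRUE), format(mzs, trim = TRUE))
  structure(list(ranking = rank_tbl, similarity = sim,
                 group_directions = dirs, components = components),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("diagnostic_report:", length(unique(x$ranking$group)), "groups,",
      nrow(x$similarity), "variables\n")
  print(utils::head(x$ranking[x$ranking$rank <= 3, ], 12))
  invisible(x)
}

#' Pairwise cosine similarity of selected loading vectors
#'
#' @param report A `diagnostic_report`.
#' @param mzs Optional m/z values (matched to the nearest variable) to
#'   subset the similarity matrix.
#' @param tol Matching tolerance in Th.
#' @return Numeric cosine matrix.
#' @export
loading_similarity <- function(report, mzs = NULL, tol = 0.02) {
  stopifnot(inherits(report, "diagnostic_report"))
  if (is.null(mzs)) return(report$similarity)
  all_mz <- as.numeric(rownames(report$similarity))
  idx <- vapply(mzs, function(m) {
    d <- abs(all_mz - m)
    if (min(d) > tol) stop("no variable within ", tol, " of m/z ", m,
                           call. = FALSE)
    which.min(d)
  }, integer(1))
  report$similarity[idx, idx, drop = FALSE]
}

#' Merge PCA-ranked diagnostics with structural annotations
#'
#' Joins the top-`k` ranked variables of each group with ion annotations (by
#' nearest m/z within `tol`); a diagnostic without a catalogue match is
#' reported as `"unassigned"` — exactly how non-assignable marker peaks stay
#' informative for classification while carrying no structural assignment.
#'
#' @param report A `diagnostic_report`.
#' @param annotations Annotation tibble (see [annotate_spectrum()]) with
#'   columns `observed_mz` (or `mz`) and `label`, optionally `peptide_id` to
#'   match annotations group-wise.
#' @param k Diagnostics kept per group (default 3).
#' @param tol Matching tolerance in Th.
#' @return Tibble: one row per diagnostic variable per group with its
#'   ranking fields and `label`.
#' @export
diagnostic_table <- function(report, annotations, k = 3L, tol = 0.02) {
  stopifnot(inherits(report, "diagnostic_report"))
  top <- report$ranking[report$ranking$rank <= k, ]
  if (nrow(top) == 0L) {
    return(dplyr::mutate(top, label = character(0)))
  }
  ann <- tibble::as_tibble(annotations)
  if (!"observed_mz" %in% names(ann) && "mz" %in% names(ann)) {
    ann$observed_mz <- ann$mz
  }
  top$label <- vapply(seq_len(nrow(top)), function(i) {
    cand <- ann
    if ("peptide_id" %in% names(cand)) {
      same <- cand$peptide_id == top$group[i]
      if (any(same)) cand <- cand[same, ]
    }
    if (nrow(cand) == 0L) return("unassigned")
    d <- abs(cand$observed_mz - top$mz[i])
    if (min(d) > tol) "unassigned" else cand$label[which.min(d)]
  }, character(1))
  top
}
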