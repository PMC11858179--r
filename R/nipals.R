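## NIPALS principal component analysis. Components are extracted one at a
## time by alternating score/loading regressions with deflation, which is
## the natural fit for spectral matrices with few samples and many
## variables. No variance scaling is applied anywhere: the data are centred
## only, which is what makes loading magnitude track fragment abundance.

.as_matrix_input <- function(x) {
  if (inherits(x, "aligned_spectra")) {
    list(x = x$x, mz = x$mz, meta = x$meta)
  } else {
    list(x = as.matrix(x), mz = attr(x, "mz"), meta = NULL)
  }
}

#' Column mean-centre a spectral matrix
#'
#' Subtracts each variable's mean, storing the means for reconstruction.
#' Centring a single row would annihilate it, so at least two rows are
#' required.
#'
#' @param x Numeric matrix (samples x variables) or `aligned_spectra`.
#' @return Same type as the input with zero-mean columns; the means are in
#'   the `column_means` attribute (matrix) or element (`aligned_spectra`).
#' @export
mean_center <- function(x) {
  if (inherits(x, "aligned_spectra")) {
    if (nrow(x$x) < 2L) stop("mean-centring needs at least 2 spectra", call. = FALSE)
    mu <- colMeans(x$x)
    x$x <- sweep(x$x, 2L, mu)
    x$column_means <- mu
    return(x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("mean-centring needs at least 2 rows", call. = FALSE)
  mu <- colMeans(x)
  out <- sweep(x, 2L, mu)
  attr(out, "column_means") <- mu
  out
}

#' Principal component analysis by NIPALS
#'
#' Iterative extraction: for each component, a score vector is seeded from
#' the column with the largest sum of squares, then loading and score are
#' alternately regressed until the relative change of the score vector drops
#' below `tol`; the component is deflated from the matrix and the next one
#' extracted. Loading vectors are unit-norm; each is sign-fixed so its
#' largest-magnitude element is positive. Explained variance per component
#' is the score vector's squared norm over the total (centred) sum of
#' squares, in percent.
#'
#' @param x Samples x variables matrix or `aligned_spectra` object.
#' @param n_components Number of components, at most `min(nrow - 1, ncol)`.
#' @param tol Relative score-change convergence threshold.
#' @param max_iter Iteration cap per component; exceeding it is an error
#'   naming the component.
#' @param center Centre columns first (stored means). Set `FALSE` only if
#'   `x` is already centred.
#' @return A `nipals_pca` object: `scores` (n x k), `loadings` (p x k,
#'   unit-norm columns), `explained_variance_pct`, `variable_mzs`,
#'   `column_means`, `totss`, `meta`, and `low_variance` flags for
#'   components beyond the effective rank.
#' @export
nipals_pca <- function(x, n_components = 2L, tol = 1e-9, max_iter = 500L,
                       center = TRUE) {
  stopifnot(tol > 0, max_iter >= 1L, n_components >= 1L)
  inp <- .as_matrix_input(x)
  X <- inp$x
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (n_components > min(nrow(X) - 1L, ncol(X))) {
    stop("n_components must be <= min(rows - 1, columns) = ",
         min(nrow(X) - 1L, ncol(X)), call. = FALSE)
  }
  mu <- rep(0, ncol(X))
  if (center) {
    mu <- colMeans(X)
    X <- sweep(X, 2L, mu)
  }
  totss <- sum(X^2)
  if (totss <= 0) stop("matrix has no variance: PCA undefined", call. = FALSE)

  n <- nrow(X); p <- ncol(X)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, p, n_components)
  evpct <- numeric(n_components)
  iters <- integer(n_components)
  low <- logical(n_components)

  for (k in seq_len(n_components)) {
    css <- colSums(X^2)
    if (max(css) <= totss * 1e-15) {
      ## matrix fully deflated: component beyond rank. Emit a unit loading
      ## orthogonal to the previous ones with zero scores, flagged.
      q <- qr.Q(qr(cbind(loadings[, seq_len(k - 1L), drop = FALSE],
                         stats::rnorm(p))))
      loadings[, k] <- q[, k]
      low[k] <- TRUE
      next
    }
    t_vec <- X[, which.max(css)]
    for (it in seq_len(max_iter)) {
      p_vec <- drop(crossprod(X, t_vec)) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- drop(X %*% p_vec)
      delta <- sqrt(sum((t_new - t_vec)^2)) / sqrt(sum(t_new^2))
      t_vec <- t_new
      if (delta < tol) break
      if (it == max_iter) {
        stop("NIPALS did not converge for component ", k, " after ",
             max_iter, " iterations", call. = FALSE)
      }
    }
    iters[k] <- it
    flip <- sign(p_vec[which.max(abs(p_vec))])
    p_vec <- p_vec * flip; t_vec <- t_vec * flip
    scores[, k] <- t_vec
    loadings[, k] <- p_vec
    evpct[k] <- 100 * sum(t_vec^2) / totss
    low[k] <- evpct[k] < 1e-8
    X <- X - tcrossprod(t_vec, p_vec)
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pct = evpct,
                 variable_mzs = inp$mz, column_means = mu, totss = totss,
                 meta = inp$meta, n_components = n_components,
                 low_variance = low, iterations = iters),
            class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat("NIPALS PCA: ", nrow(x$scores), " samples, ", nrow(x$loadings),
      " variables, ", x$n_components, " components\n", sep = "")
  cat("explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct the data matrix from a fitted model
#'
#' scores %*% t(loadings) plus the column means; with all components of a
#' full-rank fit this reproduces the input.
#'
#' @param model A `nipals_pca` object.
#' @return Numeric matrix.
#' @export
reconstruct <- function(model) {
  sweep(tcrossprod(model$scores, model$loadings), 2L, -model$column_means)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a NIPALS PCA fit
#'
#' @param x A `nipals_pca` object.
#' @param matrix `"scores"`, `"loadings"` or `"variance"`.
#' @param ... Unused.
#' @return A tibble in long format: per-sample component scores (with sample
#'   identity columns when the fit came from aligned spectra), per-variable
#'   loadings (with `mz` when available), or per-component explained
#'   variance.
#' @method tidy nipals_pca
#' @export
tidy.nipals_pca <- function(x, matrix = c("scores", "loadings", "variance"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    base <- if (!is.null(x$meta)) tibble::as_tibble(x$meta)
            else tibble::tibble(sample = seq_len(nrow(x$scores)))
    long <- tidyr::pivot_longer(
      dplyr::bind_cols(base, tibble::as_tibble(x$scores)),
      dplyr::starts_with("PC"), names_to = "component", values_to = "score")
    return(long)
  }
  if (matrix == "loadings") {
    base <- tibble::tibble(
      variable = seq_len(nrow(x$loadings)),
      mz = if (is.null(x$variable_mzs)) NA_real_ else x$variable_mzs)
    long <- tidyr::pivot_longer(
      dplyr::bind_cols(base, tibble::as_tibble(x$loadings)),
      dplyr::starts_with("PC"), names_to = "component", values_to = "loading")
    return(long)
  }
  tibble::tibble(component = paste0("PC", seq_len(x$n_components)),
                 percent = x$explained_variance_pct,
                 cumulative = cumsum(x$explained_variance_pct))
}

#' One-row summary of a NIPALS PCA fit
#'
#' @param x A `nipals_pca` object.
#' @param ... Unused.
#' @return Tibble with sample/variable/component counts and total explained
#'   variance.
#' @method glance nipals_pca
#' @export
glance.nipals_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores), n_variables = nrow(x$loadings),
                 n_components = x$n_components,
                 explained_variance_pct = sum(x$explained_variance_pct))
}
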