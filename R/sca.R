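#' Column-center a matrix
#' @param M numeric matrix with at least 2 rows.
#' @return list with `centered` (same shape, zero column means) and
#'   `means` (length-`ncol` vector removed, for back-transformation).
#' @export
center_columns <- function(M) {
  stopifnot(is.matrix(M), nrow(M) >= 2)
  mu <- colMeans(M)
  list(centered = sweep(M, 2, mu, `-`), means = mu)
}

#' PCA of a centered matrix via the SVD, with standardized scores
#'
#' With the singular value decomposition `Mc = U S V'`, the scores are
#' `T = sqrt(n - 1) * U[, 1:A]` and the loadings
#' `P = V[, 1:A] %*% S[1:A] / sqrt(n - 1)` where `n = nrow(Mc)`, so that
#' `T %*% t(P)` equals the rank-A truncation of `Mc` and every score column
#' has sample variance exactly 1. Explained variance per component is
#' `S_a^2 / sum(S^2)`. The sign of each component is fixed so that the
#' largest-magnitude loading entry is positive, making output deterministic
#' across platforms and bootstrap replicates.
#'
#' @param Mc a column-centered matrix.
#' @param A number of components to retain; must not exceed the numerical
#'   rank of `Mc`.
#' @return an `sca_result`: list with `scores` (n x A), `loadings` (m x A),
#'   `singular_values` (all), `explained_variance` (length A), `A`,
#'   `rank`, `column_means` (zeros here; filled by [analyse_effect]).
#' @export
pca_svd <- function(Mc, A) {
  stopifnot(is.matrix(Mc))
  n <- nrow(Mc)
  sv <- svd(Mc)
  tol <- max(dim(Mc)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (rank == 0L) {
    warning("matrix is identically zero; empty component result",
            call. = FALSE)
    return(structure(list(scores = matrix(0, n, 0),
                          loadings = matrix(0, ncol(Mc), 0),
                          singular_values = numeric(0),
                          explained_variance = numeric(0),
                          A = 0L, rank = 0L,
                          column_means = numeric(ncol(Mc))),
                     class = "sca_result"))
  }
  if (A > rank)
    stop("A = ", A, " exceeds the matrix rank (", rank, ")", call. = FALSE)
  idx <- seq_len(A)
  Tm <- sqrt(n - 1) * sv$u[, idx, drop = FALSE]
  P <- sv$v[, idx, drop = FALSE] %*%
    diag(sv$d[idx] / sqrt(n - 1), A, A)
  # deterministic sign: largest |loading| entry positive per component
  for (a in idx) {
    piv <- which.max(abs(P[, a]))
    if (P[piv, a] < 0) {
      P[, a] <- -P[, a]
      Tm[, a] <- -Tm[, a]
    }
  }
  colnames(Tm) <- colnames(P) <- paste0("PC", idx)
  structure(list(scores = Tm, loadings = P,
                 singular_values = sv$d,
                 explained_variance = sv$d[idx]^2 / sum(sv$d^2),
                 A = as.integer(A), rank = rank,
                 column_means = numeric(ncol(Mc))),
            class = "sca_result")
}

#' Summarise an effect matrix by centered PCA
#'
#' In `trajectory` geometry the IHK x J matrix is analysed directly: score
#' rows are (subject, treatment, time) cells -- for fixed-effect matrices
#' the scores repeat across subjects and trace the population-level
#' temporal pattern per treatment -- and loadings associate each response
#' with the pattern. In `individual` geometry the matrix is first reshaped
#' to I x HKJ ([reshape_individual]) so each score row is one subject.
#'
#' @param M IHK x J effect matrix in canonical row order.
#' @param geometry `"trajectory"` or `"individual"`.
#' @param A components to retain (capped at the matrix rank when
#'   `cap_A = TRUE`).
#' @param dims an [asca_dims] list.
#' @param labels optional data.frame of row labels (subject, treatment,
#'   time) in canonical order.
#' @param cap_A if TRUE (default) silently reduce `A` to the matrix rank;
#'   rank-deficient effect matrices (e.g. a quadratic time term spans rank
#'   2) are the norm rather than the exception.
#' @return an `sca_result` with `geometry`, `row_labels` and `col_labels`
#'   attached.
#' @export
analyse_effect <- function(M, geometry = c("trajectory", "individual"),
                           A = 3L, dims = NULL, labels = NULL,
                           cap_A = TRUE) {
  geometry <- match.arg(geometry)
  col_labels <- colnames(M)
  if (geometry == "individual") {
    stopifnot(!is.null(dims))
    subj <- if (!is.null(labels)) unique(labels$subject) else
      paste0("i", seq_len(dims$I))
    lbl <- data.frame(subject = subj)
    grid <- expand.grid(response = seq_len(dims$J),
                        time = seq_len(dims$K),
                        treatment = seq_len(dims$H))[, 3:1]
    cl <- if (!is.null(col_labels))
      paste0(col_labels[grid$response], "@h", grid$treatment,
             ".k", grid$time) else NULL
    M <- reshape_individual(M, dims)
    colnames(M) <- cl
    col_labels <- cl
    labels <- lbl
  }
  cc <- center_columns(M)
  d <- svd(cc$centered, nu = 0, nv = 0)$d
  rank <- sum(d > max(dim(M)) * .Machine$double.eps * max(d, 0))
  if (cap_A && rank > 0) A <- min(A, rank)
  res <- pca_svd(cc$centered, A)
  res$column_means <- cc$means
  res$geometry <- geometry
  res$row_labels <- labels
  res$col_labels <- col_labels
  if (!is.null(col_labels)) rownames(res$loadings) <- col_labels
  res
}

#' @export
print.sca_result <- function(x, ...) {
  cat(sprintf("sca_result (%s): %d x %d, A=%d\n",
              if (is.null(x$geometry)) "matrix" else x$geometry,
              nrow(x$scores), nrow(x$loadings), x$A))
  if (x$A > 0)
    cat("explained variance:",
        paste0(sprintf("PC%d %.1f%%", seq_len(x$A),
                       100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format export of scores/loadings for plotting
#'
#' @param res an `sca_result`.
#' @param ci optional `bootstrap_result` from [bootstrap_pipeline] whose
#'   bounds are merged in as `lower`/`upper`.
#' @return data.frame with columns `what` (score/loading), `component`,
#'   `row`, `label`, `value` and, when `ci` is given, `lower`, `upper`.
#' @export
sca_plot_data <- function(res, ci = NULL) {
  stopifnot(inherits(res, "sca_result"))
  mk <- function(mat, what, labels) {
    if (ncol(mat) == 0) return(NULL)
    comp <- colnames(mat)
    if (is.null(comp)) comp <- paste0("PC", seq_len(ncol(mat)))
    df <- expand.grid(row = seq_len(nrow(mat)),
                      component = comp,
                      stringsAsFactors = FALSE)
    df$what <- what
    df$value <- as.vector(mat)
    df$label <- if (!is.null(labels)) labels[df$row] else as.character(df$row)
    df[, c("what", "component", "row", "label", "value")]
  }
  score_lab <- if (!is.null(res$row_labels))
    do.call(paste, c(res$row_labels, sep = "/")) else NULL
  out <- rbind(mk(res$scores, "score", score_lab),
               mk(res$loadings, "loading", res$col_labels))
  if (!is.null(ci)) {
    lo <- rbind(mk(ci$score_bounds$lower, "score", score_lab),
                mk(ci$loading_bounds$lower, "loading", res$col_labels))
    hi <- rbind(mk(ci$score_bounds$upper, "score", score_lab),
                mk(ci$loading_bounds$upper, "loading", res$col_labels))
    out$lower <- lo$value
    out$upper <- hi$value
  }
  out
}

#' Plot an `sca_result`
#'
#' Base-graphics convenience plot: score trajectories over time per
#' treatment (trajectory geometry), or a PC1/PC2 subject scatter
#' (individual geometry).
#'
#' @param x an `sca_result` from [analyse_effect] with row labels.
#' @param components which components to draw (trajectory mode).
#' @param ... passed to [graphics::matplot] / [graphics::plot].
#' @export
plot.sca_result <- function(x, components = seq_len(min(2, x$A)), ...) {
  if (x$A == 0) {
    warning("empty result; nothing to plot")
    return(invisible(x))
  }
  if (identical(x$geometry, "individual")) {
    a <- components[1]
    b <- if (length(components) > 1) components[2] else a
    graphics::plot(x$scores[, a], x$scores[, b],
                   xlab = sprintf("PC%d (%.1f%%)", a,
                                  100 * x$explained_variance[a]),
                   ylab = sprintf("PC%d (%.1f%%)", b,
                                  100 * x$explained_variance[b]), ...)
    if (!is.null(x$row_labels))
      graphics::text(x$scores[, a], x$scores[, b],
                     labels = x$row_labels$subject, pos = 3, cex = 0.7)
  } else {
    if (is.null(x$row_labels))
      stop("trajectory plot needs row labels", call. = FALSE)
    lb <- x$row_labels
    first <- lb$subject == lb$subject[1]
    for (a in components) {
      sc <- x$scores[first, a]
      tm <- lb$time[first]
      trt <- lb$treatment[first]
      wide <- do.call(cbind, lapply(unique(trt),
                                    function(h) sc[trt == h]))
      graphics::matplot(unique(tm), wide, type = "b", pch = 16,
                        xlab = "time",
                        ylab = sprintf("PC%d score (%.1f%%)", a,
                                       100 * x$explained_variance[a]), ...)
      graphics::legend("topleft", legend = unique(trt), bty = "n",
                       col = seq_along(unique(trt)), lty = seq_along(unique(trt)))
    }
  }
  invisible(x)
}
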