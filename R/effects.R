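#' Effect matrix for one model term group
#'
#' Forms the IHK x J matrix attributable to one term group by multiplying
#' the selected design columns with the matching coefficient rows: for
#' fixed parts, `X[, cols] %*% B[cols, ]`; for random parts, the analogous
#' per-subject product of `Z` columns with the subject's BLUP rows of
#' `Gamma`. All design rows are populated (model predictions), including
#' rows whose observation was missing.
#'
#' @param fit a [fit_all] result.
#' @param which `"baseline"`, `"time"` or `"time_treatment"`.
#' @param part `"fixed"` or `"random"`.
#' @return an IHK x J numeric matrix. If the requested random term group is
#'   absent from the random structure (e.g. `intercept_only`), a zero
#'   matrix is returned.
#' @export
effect_matrix <- function(fit,
                          which = c("baseline", "time", "time_treatment"),
                          part = c("fixed", "random")) {
  stopifnot(inherits(fit, "multivariate_fit"))
  which <- match.arg(which)
  part <- match.arg(part)
  des <- fit$design
  grp <- if (which == "baseline") "intercept" else which

  if (part == "fixed") {
    cols <- des$column_groups[[grp]]
    if (is.null(cols)) stop("unknown column group: ", grp, call. = FALSE)
    M <- des$X[, cols, drop = FALSE] %*% fit$B[cols, , drop = FALSE]
  } else {
    cols <- des$z_column_groups[[grp]]
    if (is.null(cols)) {
      M <- matrix(0, nrow(des$X), length(fit$responses))
      colnames(M) <- fit$responses
      return(M)
    }
    q <- des$q
    idx <- as.integer(des$subject)           # subject block per row
    M <- matrix(0, nrow(des$Z), length(fit$responses))
    for (cc in cols) {
      # Gamma row (i-1)*q + cc holds coefficient cc of subject i
      M <- M + des$Z[, cc] * fit$Gamma[(idx - 1L) * q + cc, , drop = FALSE]
    }
  }
  colnames(M) <- fit$responses
  M
}

effect_codes <- c(M0f = "baseline.fixed", MTf = "time.fixed",
                  MTGf = "time_treatment.fixed",
                  M0r = "baseline.random", MTr = "time.random",
                  MTGr = "time_treatment.random")

#' Decompose the response matrix into additive effect matrices
#'
#' Splits the model reconstruction of `Y` into the six named effect
#' matrices -- baseline, time and time-treatment interaction, each for the
#' fixed and the random part -- plus the residual matrix `E`. On observed
#' cells the seven matrices sum to `Y` exactly; `E` is missing where the
#' observation was missing.
#'
#' @param fit a [fit_all] result.
#' @return an `effect_matrices` object: list with components `M0f`, `MTf`,
#'   `MTGf`, `M0r`, `MTr`, `MTGr`, `E`, plus `labels` (subject, treatment,
#'   time per row) and `dims`.
#' @export
decompose_effects <- function(fit) {
  stopifnot(inherits(fit, "multivariate_fit"))
  out <- lapply(effect_codes, function(code) {
    parts <- strsplit(code, ".", fixed = TRUE)[[1]]
    effect_matrix(fit, parts[1], parts[2])
  })
  recon <- Reduce(`+`, out)
  out$E <- fit$Y - recon
  out$labels <- data.frame(subject = fit$data$subject,
                           treatment = fit$data$treatment,
                           time = fit$data$time)
  out$dims <- fit$dims
  class(out) <- "effect_matrices"
  out
}

#' @export
print.effect_matrices <- function(x, ...) {
  cat(sprintf("effect_matrices: %d x %d (%s + E)\n",
              nrow(x$M0f), ncol(x$M0f),
              paste(names(effect_codes), collapse = " + ")))
  invisible(x)
}

#' Sum effect matrices elementwise
#'
#' Used to analyse combined effects, e.g. `MTf + MTGf` summarising the
#' overall treatment-period response.
#'
#' @param matrices list of conforming effect matrices (or an
#'   `effect_matrices` object together with `which` names).
#' @param which optional character vector of component names when
#'   `matrices` is an `effect_matrices` object (e.g. `c("MTf", "MTGf")`).
#' @return the elementwise sum with labels preserved.
#' @export
combine_effects <- function(matrices, which = NULL) {
  if (inherits(matrices, "effect_matrices")) {
    stopifnot(!is.null(which))
    matrices <- unclass(matrices)[which]
    if (any(vapply(matrices, is.null, logical(1))))
      stop("unknown effect name(s): ",
           paste(which[vapply(matrices, is.null, logical(1))],
                 collapse = ", "), call. = FALSE)
  }
  stopifnot(length(matrices) >= 1)
  ref <- dim(matrices[[1]])
  for (m in matrices)
    if (!identical(dim(m), ref))
      stop("effect matrices have mismatched shapes", call. = FALSE)
  Reduce(`+`, matrices)
}

#' Reshape an effect matrix from IHK x J to I x HKJ
#'
#' Row `i` of the result concatenates subject `i`'s rows of `M` in
#' treatment-major order, then ascending time, with the `J` response
#' columns as the fastest axis within each (treatment, time) cell. PCA of
#' the reshaped matrix yields one score point per subject (the
#' "individual" score plot geometry). The reshape is a bijection; see
#' [reshape_trajectory] for the inverse.
#'
#' @param M IHK x J matrix in canonical row order.
#' @param dims an [asca_dims] list.
#' @return an I x (H*K*J) matrix.
#' @export
reshape_individual <- function(M, dims) {
  n <- dims$I * dims$H * dims$K
  if (nrow(M) != n)
    stop(sprintf("expected %d rows (I*H*K), got %d", n, nrow(M)),
         call. = FALSE)
  out <- matrix(NA_real_, dims$I, dims$H * dims$K * dims$J)
  hk <- dims$H * dims$K
  for (i in seq_len(dims$I)) {
    rows <- ((i - 1L) * hk + 1L):(i * hk)
    out[i, ] <- as.vector(t(M[rows, , drop = FALSE]))
  }
  out
}

#' Inverse of [reshape_individual]
#' @param Mi an I x HKJ matrix.
#' @param dims an [asca_dims] list.
#' @return the IHK x J matrix in canonical row order.
#' @export
reshape_trajectory <- function(Mi, dims) {
  if (nrow(Mi) != dims$I || ncol(Mi) != dims$H * dims$K * dims$J)
    stop("shape does not match dims", call. = FALSE)
  hk <- dims$H * dims$K
  out <- matrix(NA_real_, dims$I * hk, dims$J)
  for (i in seq_len(dims$I)) {
    rows <- ((i - 1L) * hk + 1L):(i * hk)
    out[rows, ] <- t(matrix(Mi[i, ], dims$J, hk))
  }
  out
}

#' Write an effect matrix as a labelled CSV
#' @param M IHK x J effect matrix.
#' @param labels data.frame with subject/treatment/time per row.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_effect_csv <- function(M, labels, path) {
  utils::write.csv(cbind(labels, as.data.frame(M)), path, row.names = FALSE)
  invisible(path)
}
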