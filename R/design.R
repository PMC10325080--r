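#' Time-basis specification
#'
#' Describes the basis expansion of the numeric time variable used by the
#' per-response mixed models: raw polynomials (columns t, t^2, ...) or a
#' natural cubic spline with a chosen number of degrees of freedom.
#'
#' @param kind `"polynomial"` or `"natural_spline"`.
#' @param degree_or_df polynomial degree, or spline degrees of freedom.
#' @param interior_knots optional interior knot locations (spline only);
#'   default places `df - 1` knots at equally spaced quantiles of the
#'   observed times.
#' @param boundary_knots optional length-2 boundary knots (spline only);
#'   default is the range of the observed times.
#' @return a `time_basis` object.
#' @export
time_basis <- function(kind = c("polynomial", "natural_spline"),
                       degree_or_df = 2L,
                       interior_knots = NULL, boundary_knots = NULL) {
  kind <- match.arg(kind)
  degree_or_df <- as.integer(degree_or_df)
  if (degree_or_df < 1L) stop("degree_or_df must be >= 1", call. = FALSE)
  if (kind == "polynomial" && (!is.null(interior_knots) || !is.null(boundary_knots)))
    stop("knots are only meaningful for spline bases", call. = FALSE)
  if (!is.null(boundary_knots)) {
    stopifnot(length(boundary_knots) == 2)
    if (diff(boundary_knots) <= 0)
      stop("boundary_knots must be strictly increasing", call. = FALSE)
    if (!is.null(interior_knots) &&
        (any(interior_knots <= boundary_knots[1]) ||
         any(interior_knots >= boundary_knots[2])))
      stop("interior knots must lie strictly inside the boundary knots",
           call. = FALSE)
  }
  structure(list(kind = kind, degree_or_df = degree_or_df,
                 interior_knots = interior_knots,
                 boundary_knots = boundary_knots),
            class = "time_basis")
}

#' Raw polynomial basis of time
#'
#' Column m holds `t^m`, m = 1..degree; no intercept column.
#'
#' @param t numeric vector of times.
#' @param degree polynomial degree (>= 1).
#' @return a `length(t) x degree` matrix with columns `t`, `t^2`, ...
#' @examples
#' polynomial_basis(0:3, 2)
#' @export
polynomial_basis <- function(t, degree) {
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  out <- outer(t, seq_len(degree), `^`)
  colnames(out) <- paste0("t", ifelse(seq_len(degree) == 1, "",
                                      seq_len(degree)))
  out
}

#' Natural cubic spline basis of time
#'
#' A natural cubic spline is piecewise cubic with continuous first and
#' second derivatives at the knots and is constrained to be linear beyond
#' the boundary knots. The basis (from [splines::ns]) is anchored so every
#' column is exactly 0 at `anchor` (default: the left boundary knot); with
#' that anchoring the model intercept keeps its baseline meaning and
#' time-by-treatment interaction columns vanish at baseline, preserving the
#' assumption of no treatment difference before the challenge.
#'
#' @param t numeric vector of evaluation times.
#' @param df spline degrees of freedom (number of basis columns, >= 1).
#' @param boundary_knots length-2 numeric; default `range(t)`.
#' @param interior_knots numeric vector of interior knots; default `df - 1`
#'   equally spaced quantiles of the distinct values of `t`.
#' @param anchor time at which all basis columns are pinned to zero.
#' @return a `length(t) x df` matrix; attributes `interior_knots`,
#'   `boundary_knots` and `anchor` record the realized configuration.
#' @export
natural_spline_basis <- function(t, df, boundary_knots = NULL,
                                 interior_knots = NULL, anchor = NULL) {
  df <- as.integer(df)
  ut <- sort(unique(t))
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  # with default (data-driven) knots, the basis cannot have full column
  # rank unless there are at least df distinct times; explicit knots may
  # be evaluated on any grid
  if (df > length(ut) && (is.null(boundary_knots) || is.null(interior_knots)))
    stop("df (", df, ") exceeds the number of distinct time values (",
         length(ut), ")", call. = FALSE)
  if (is.null(boundary_knots)) boundary_knots <- range(ut)
  if (is.null(interior_knots)) {
    if (df > 1)
      interior_knots <- stats::quantile(ut, probs = seq_len(df - 1) / df,
                                        names = FALSE, type = 7)
    else
      interior_knots <- numeric(0)
  }
  if (is.null(anchor)) anchor <- boundary_knots[1]
  b <- splines::ns(t, knots = interior_knots,
                   Boundary.knots = boundary_knots, intercept = FALSE)
  b0 <- splines::ns(anchor, knots = interior_knots,
                    Boundary.knots = boundary_knots, intercept = FALSE)
  out <- sweep(unclass(b), 2, as.numeric(b0), `-`)
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  attr(out, "interior_knots") <- as.numeric(interior_knots)
  attr(out, "boundary_knots") <- as.numeric(boundary_knots)
  attr(out, "anchor") <- anchor
  out
}

#' Evaluate a `time_basis` on a set of times
#' @param basis a [time_basis].
#' @param t numeric vector of times.
#' @return basis matrix, one column per basis function.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "time_basis"))
  if (basis$kind == "polynomial")
    polynomial_basis(t, basis$degree_or_df)
  else
    natural_spline_basis(t, basis$degree_or_df,
                         boundary_knots = basis$boundary_knots,
                         interior_knots = basis$interior_knots)
}

#' Sum-coded treatment contrasts
#'
#' For H = 2 treatments the first level in sorted label order is coded +1
#' and the second -1, so treatment effects are expressed relative to the
#' mean over the two arms. For H > 2, H - 1 sum-coded contrast columns are
#' produced (each level against the grand mean, last level as the
#' negative reference row).
#'
#' @param levels treatment labels (unique, >= 2).
#' @return a `treatment_coding` object: list with `levels` (sorted) and
#'   `codes`, an H x (H-1) contrast matrix whose columns each sum to 0.
#' @examples
#' sum_code(c("A", "B"))$codes
#' @export
sum_code <- function(levels) {
  levels <- sort(unique(as.character(levels)))
  H <- length(levels)
  if (H < 2) stop("need at least two treatment levels", call. = FALSE)
  if (H == 2) {
    codes <- matrix(c(1, -1), ncol = 1, dimnames = list(levels, "g"))
  } else {
    codes <- stats::contr.sum(H)
    dimnames(codes) <- list(levels, paste0("g", seq_len(H - 1)))
  }
  structure(list(levels = levels, codes = codes), class = "treatment_coding")
}

#' Build the fixed and random design matrices
#'
#' Constructs the stacked design for the per-response mixed models. The
#' fixed design `X` has columns `[1 | basis(t) | basis(t) * g]` in that
#' order: an intercept, the time-basis columns, and each basis column
#' multiplied by the sum-coded treatment contrast(s). There is deliberately
#' no treatment main-effect column: with no treatment difference at
#' baseline, treatment can only act through its interaction with time.
#' The random design `Z` mirrors `X` per subject (`mirror_fixed`), keeps
#' only the intercept (`intercept_only`), or is empty (`none`).
#'
#' @param data a [long_dataset] in canonical row order (complete grid not
#'   required, but rows must follow subject > treatment > time order).
#' @param basis a [time_basis].
#' @param random_structure one of `"mirror_fixed"`, `"intercept_only"`,
#'   `"none"`.
#' @return a `design_bundle`: list with `X` (IHK x p), `Z` (IHK x q row
#'   blocks; conceptually block-diagonal by subject), `subject` (factor,
#'   canonical level order), `column_groups` / `z_column_groups` (named
#'   partitions into intercept / time / time_treatment), `p`, `q`,
#'   `coding`, `basis`.
#' @examples
#' df <- expand.grid(subject = "s1", treatment = c("A", "B"), time = 0:3)
#' df$y <- 0
#' ld <- long_dataset(df, "subject", "treatment", "time")
#' build_design(ld, time_basis("polynomial", 2))$X
#' @export
build_design <- function(data, basis,
                         random_structure = c("mirror_fixed",
                                              "intercept_only", "none")) {
  stopifnot(inherits(data, "long_dataset"), inherits(basis, "time_basis"))
  random_structure <- match.arg(random_structure)

  coding <- sum_code(unique(data$treatment))
  Bmat <- eval_basis(basis, data$time)
  nb <- ncol(Bmat)
  G <- coding$codes[data$treatment, , drop = FALSE]  # n x (H-1)

  inter <- do.call(cbind, lapply(seq_len(ncol(G)), function(c_i)
    Bmat * G[, c_i]))
  colnames(inter) <- as.vector(outer(colnames(Bmat), colnames(coding$codes),
                                     paste, sep = ":"))
  X <- cbind(`(Intercept)` = 1, Bmat, inter)
  p <- ncol(X)
  column_groups <- list(
    intercept = 1L,
    time = seq.int(2L, 1L + nb),
    time_treatment = seq.int(2L + nb, p))

  Z <- switch(random_structure,
              mirror_fixed = X,
              intercept_only = X[, 1L, drop = FALSE],
              none = X[, 0L, drop = FALSE])
  z_column_groups <- switch(random_structure,
                            mirror_fixed = column_groups,
                            intercept_only = list(intercept = 1L),
                            none = list())

  structure(list(X = X, Z = Z,
                 subject = factor(data$subject,
                                  levels = unique(data$subject)),
                 column_groups = column_groups,
                 z_column_groups = z_column_groups,
                 p = p, q = ncol(Z),
                 random_structure = random_structure,
                 coding = coding, basis = basis,
                 time = data$time),
            class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat(sprintf("design_bundle: %d rows, p=%d fixed, q=%d random (%s), basis=%s(%d)\n",
              nrow(x$X), x$p, x$q, x$random_structure,
              x$basis$kind, x$basis$degree_or_df))
  invisible(x)
}
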