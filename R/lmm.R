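#' Fit one response column by REML
#'
#' Fits the linear mixed model `y = X beta + Z_i gamma_i + eps` for a single
#' response, with unstructured random-effects covariance `D` and iid
#' residuals, via [lme4::lmer] (REML). Design columns are rescaled to unit
#' maximum absolute value before optimisation -- raw polynomial columns such
#' as t^2 on a 0..10 grid are badly conditioned otherwise -- and all
#' estimates are transformed back to the original column scale, which is an
#' exact reparameterisation of the same model family.
#'
#' Rows with missing `y` are excluded from estimation; the design rows are
#' retained so that effect matrices can later be populated with model
#' predictions for every cell of the grid.
#'
#' @param y numeric response vector aligned with the design rows.
#' @param design a [build_design] result.
#' @param start optional warm-start value for the covariance parameter
#'   vector (`theta` on the rescaled column scale), e.g. from a previous
#'   fit on similar data. Speeds up bootstrap refits considerably.
#' @param fast if TRUE, relax the covariance-parameter optimiser tolerance
#'   (absolute 1e-4 instead of 1e-6). Used for bootstrap replicates, where
#'   percentile bounds do not require full REML precision; reference fits
#'   keep the default.
#' @return a `univariate_fit`: list with `beta` (p), `gamma` (I x q BLUPs,
#'   canonical subject order), `D_hat` (q x q), `sigma2_eps`, `converged`,
#'   `singular`, `reml_crit`, `n_obs`, `theta` (for warm starts) and
#'   `fitted_fixed` / `fitted_random` over all design rows.
#' @export
fit_univariate <- function(y, design, start = NULL, fast = FALSE) {
  stopifnot(inherits(design, "design_bundle"))
  X <- design$X
  Z <- design$Z
  n <- nrow(X)
  stopifnot(length(y) == n)
  obs <- !is.na(y)
  if (!any(obs)) stop("response is entirely missing", call. = FALSE)

  subj <- design$subject
  I <- nlevels(subj)
  p <- design$p
  q <- design$q

  if (q == 0L) {
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    res <- y[obs] - X[obs, , drop = FALSE] %*% beta
    out <- list(beta = as.numeric(beta),
                gamma = matrix(0, I, 0),
                D_hat = matrix(0, 0, 0),
                sigma2_eps = sum(res^2) / max(1, sum(obs) - fit$rank),
                converged = TRUE, singular = FALSE,
                reml_crit = NA_real_, n_obs = sum(obs), theta = NULL)
    return(finish_fit(out, design, y))
  }

  sx <- apply(abs(X), 2, max); sx[sx == 0] <- 1
  sz <- apply(abs(Z), 2, max); sz[sz == 0] <- 1
  Xs <- sweep(X, 2, sx, `/`)
  Zs <- sweep(Z, 2, sz, `/`)

  xn <- paste0("x", seq_len(p))
  zn <- paste0("z", seq_len(q))
  df <- as.data.frame(Xs); names(df) <- xn
  dz <- as.data.frame(Zs); names(dz) <- zn
  df <- cbind(df, dz)
  df$.subject <- subj
  df$.y <- y
  df <- df[obs, , drop = FALSE]

  fml <- stats::as.formula(paste(
    ".y ~ 0 +", paste(xn, collapse = " + "),
    "+ (0 +", paste(zn, collapse = " + "), "| .subject)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            optCtrl = if (fast)
                              list(xtol_abs = 1e-4, ftol_abs = 1e-4)
                            else list())

  warned <- FALSE
  m <- withCallingHandlers(
    lme4::lmer(fml, data = df, REML = TRUE, control = ctrl,
               start = if (!is.null(start)) list(theta = start)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))

  conv_code <- m@optinfo$conv$opt
  converged <- (is.null(conv_code) || conv_code == 0) && !warned
  if (!converged)
    warning("mixed-model fit did not fully converge (flagged, not dropped)",
            call. = FALSE)

  beta_s <- lme4::fixef(m)
  beta <- as.numeric(beta_s) / sx

  re <- lme4::ranef(m)$.subject
  gamma <- matrix(0, I, q, dimnames = list(levels(subj), zn))
  gamma[rownames(re), ] <- as.matrix(re)[, zn]
  gamma <- sweep(gamma, 2, sz, `/`)

  vc <- lme4::VarCorr(m)$.subject
  D_s <- matrix(as.numeric(vc), q, q)
  D <- diag(1 / sz, q) %*% D_s %*% diag(1 / sz, q)
  dimnames(D) <- list(colnames(Z), colnames(Z))
  dimnames(gamma) <- list(levels(subj), colnames(Z))
  names(beta) <- colnames(X)

  out <- list(beta = beta, gamma = gamma, D_hat = D,
              sigma2_eps = lme4::getME(m, "sigma")^2,
              converged = converged,
              singular = lme4::isSingular(m),
              reml_crit = lme4::REMLcrit(m),
              n_obs = sum(obs),
              theta = lme4::getME(m, "theta"))
  finish_fit(out, design, y)
}

# attach fitted components and residuals over all design rows
finish_fit <- function(out, design, y) {
  X <- design$X; Z <- design$Z
  idx <- as.integer(design$subject)
  out$fitted_fixed <- as.numeric(X %*% out$beta)
  out$fitted_random <- if (design$q > 0)
    rowSums(Z * out$gamma[idx, , drop = FALSE]) else numeric(nrow(X))
  out$residuals <- y - out$fitted_fixed - out$fitted_random
  class(out) <- "univariate_fit"
  out
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("univariate_fit: p=%d, q=%d, sigma2=%.4g, converged=%s, singular=%s\n",
              length(x$beta), ncol(x$gamma), x$sigma2_eps,
              x$converged, x$singular))
  invisible(x)
}

#' Fit every response column and assemble the multivariate matrices
#'
#' Applies [fit_univariate] to each of the `J` response columns using the
#' shared design, then collects the fixed-effect coefficients into the
#' `p x J` matrix `B` and the per-subject random-effect predictions (BLUPs)
#' into the `Iq x J` matrix `Gamma` (subject-major row blocks of `q`).
#' Columns are statistically independent fits; later variables are
#' warm-started from the previous variable's covariance parameters, which
#' changes only optimisation speed, not the REML solution.
#'
#' @param data a [long_dataset] in canonical order.
#' @param design the matching [build_design] result.
#' @param start_thetas optional list of warm-start `theta` vectors, one per
#'   response (e.g. from a reference fit when bootstrapping).
#' @param warm_start chain warm starts across variables (default TRUE).
#' @param fast passed to [fit_univariate].
#' @return a `multivariate_fit`: list with `B`, `Gamma`, `per_variable`
#'   (list of `univariate_fit`), `design`, `data`, `Y`, `dims`.
#' @export
fit_all <- function(data, design, start_thetas = NULL, warm_start = TRUE,
                    fast = FALSE) {
  stopifnot(inherits(data, "long_dataset"), inherits(design, "design_bundle"))
  if (nrow(design$X) != nrow(data))
    stop("design and data row counts differ", call. = FALSE)
  Y <- response_matrix(data)
  responses <- colnames(Y)
  J <- ncol(Y)
  dims <- asca_dims(data)

  fits <- vector("list", J)
  names(fits) <- responses
  prev_theta <- NULL
  for (j in seq_len(J)) {
    start <- if (!is.null(start_thetas)) start_thetas[[j]]
             else if (warm_start) prev_theta
    fits[[j]] <- tryCatch(
      fit_univariate(Y[, j], design, start = start, fast = fast),
      error = function(e) stop("response '", responses[j], "': ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(fits[[j]]$theta)) prev_theta <- fits[[j]]$theta
  }

  B <- vapply(fits, `[[`, numeric(design$p), "beta")
  dim(B) <- c(design$p, J)
  dimnames(B) <- list(colnames(design$X), responses)
  Gamma <- vapply(fits, function(f) as.vector(t(f$gamma)),
                  numeric(dims$I * design$q))
  dim(Gamma) <- c(dims$I * design$q, J)
  dimnames(Gamma) <- list(NULL, responses)

  structure(list(B = B, Gamma = Gamma, per_variable = fits,
                 design = design, data = data, Y = Y, dims = dims,
                 responses = responses),
            class = "multivariate_fit")
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat(sprintf("multivariate_fit: J=%d responses, p=%d, q=%d, I=%d subjects\n",
              length(x$responses), x$design$p, x$design$q, x$dims$I))
  nc <- sum(!vapply(x$per_variable, `[[`, logical(1), "converged"))
  ns <- sum(vapply(x$per_variable, `[[`, logical(1), "singular"))
  cat(sprintf("  non-converged: %d, singular: %d\n", nc, ns))
  invisible(x)
}

#' Per-variable fit summary table
#' @param fit a `multivariate_fit`.
#' @return data.frame with one row per response: convergence and
#'   singularity flags, residual variance, REML criterion.
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "multivariate_fit"))
  data.frame(
    response = as.character(fit$responses),
    converged = vapply(fit$per_variable, `[[`, logical(1), "converged"),
    singular = vapply(fit$per_variable, `[[`, logical(1), "singular"),
    sigma2_eps = vapply(fit$per_variable, `[[`, numeric(1), "sigma2_eps"),
    reml_crit = vapply(fit$per_variable, `[[`, numeric(1), "reml_crit"),
    row.names = NULL)
}
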