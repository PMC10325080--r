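#' Subject-level bootstrap resampling
#'
#' Draws `n_boot` resampled datasets. The resampling unit is the subject:
#' a drawn subject carries all of its rows, across every treatment
#' occasion, into the replicate. Duplicated draws receive fresh unique
#' subject ids (`<orig>#<slot>`) so the mixed model treats them as
#' distinct grouping units -- without relabelling, duplicated subjects
#' would be pooled into one random-effect level and the replicate model
#' would be wrong.
#'
#' Replicate `r` uses a deterministic substream derived from
#' `(seed, r)`, so individual replicates are reproducible in isolation.
#'
#' @param data a [long_dataset].
#' @param n_boot number of replicates (>= 1).
#' @param seed integer master seed.
#' @return list of `n_boot` [long_dataset] objects, each with the original
#'   number of subjects.
#' @export
bootstrap_subjects <- function(data, n_boot, seed) {
  stopifnot(inherits(data, "long_dataset"), n_boot >= 1)
  subjects <- unique(data$subject)
  I <- length(subjects)
  lod <- attr(data, "lod")
  responses <- attr(data, "responses")
  lapply(seq_len(n_boot), function(r) {
    set.seed(substream_seed(seed, r))
    draw <- sample.int(I, I, replace = TRUE)
    pieces <- lapply(seq_len(I), function(slot) {
      rows <- data$subject == subjects[draw[slot]]
      piece <- as.data.frame(data)[rows, , drop = FALSE]
      piece$subject <- sprintf("%s#%02d", piece$subject, slot)
      piece
    })
    boot <- do.call(rbind, pieces)
    long_dataset(boot, "subject", "treatment", "time",
                 responses = responses)
  })
}

# deterministic 32-bit substream seed from (master seed, replicate)
substream_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + as.double(r) * 16807) %% 2147483647)
}

#' Orthogonal Procrustes alignment of a replicate to the reference
#'
#' Finds the orthogonal matrix `R` minimising
#' `||P_boot %*% R - P_ref||_F` (closed form: `R = W %*% t(V)` from the SVD
#' `t(P_boot) %*% P_ref = W S V'`), then applies the same rotation to the
#' replicate's scores. Aligning on the loadings and carrying the rotation
#' to the scores keeps the replicate's fitted subspace intact (rotations
#' preserve explained variance) while removing the arbitrary rotation and
#' reflection freedom of the SVD between replicates.
#'
#' @param P_boot,P_ref m x A loading matrices (replicate, reference).
#' @param T_boot n x A replicate score matrix.
#' @return list with `loadings` (`P_boot %*% R`), `scores`
#'   (`T_boot %*% R`) and `rotation` (`R`).
#' @export
procrustes_align <- function(P_boot, P_ref, T_boot) {
  if (!all(dim(P_boot) == dim(P_ref)))
    stop("loading matrices have different shapes", call. = FALSE)
  sv <- svd(crossprod(P_boot, P_ref))
  R <- sv$u %*% t(sv$v)
  list(loadings = P_boot %*% R, scores = T_boot %*% R, rotation = R)
}

#' Percentile confidence bounds from aligned bootstrap replicates
#'
#' Entrywise empirical percentiles (inverse-ECDF, i.e. `type = 1` order
#' statistics, so two replicates give min/max bounds) at
#' `(1 - level) / 2` and `1 - (1 - level) / 2`.
#'
#' @param score_reps,loading_reps 3-d arrays, replicate x row x component.
#' @param level nominal coverage, default 0.95.
#' @param n_failed count of dropped replicates, recorded in the result.
#' @return a `bootstrap_result`: `score_bounds` and `loading_bounds`, each
#'   a list of `lower`/`upper` matrices; `n_boot`, `level`,
#'   `replicate_failures`.
#' @export
percentile_ci <- function(score_reps, loading_reps, level = 0.95,
                          n_failed = 0L) {
  stopifnot(length(dim(score_reps)) == 3, length(dim(loading_reps)) == 3)
  if (dim(score_reps)[1] < 2)
    stop("need at least 2 successful replicates", call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  bnd <- function(arr) {
    lo <- apply(arr, c(2, 3), stats::quantile, probs = probs[1],
                type = 1, names = FALSE)
    hi <- apply(arr, c(2, 3), stats::quantile, probs = probs[2],
                type = 1, names = FALSE)
    list(lower = lo, upper = hi)
  }
  structure(list(score_bounds = bnd(score_reps),
                 loading_bounds = bnd(loading_reps),
                 n_boot = dim(score_reps)[1], level = level,
                 replicate_failures = n_failed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d replicates (%d failed), %.0f%% percentile CIs\n",
              x$n_boot, x$replicate_failures, 100 * x$level))
  invisible(x)
}

#' End-to-end bootstrap confidence intervals for scores and loadings
#'
#' Fits the reference model on the full data, then for each subject-level
#' bootstrap replicate refits the model, recomputes the requested effect
#' summary, rotates it onto the reference by orthogonal Procrustes
#' analysis of the loadings, and finally takes entrywise percentile bounds
#' across the aligned replicates. Replicates in which any response's fit
#' errors or fails to converge are dropped and counted; more than 50%
#' failures aborts with an error (the model is unstable on this data).
#'
#' @param data a [long_dataset].
#' @param basis a [time_basis].
#' @param effects one effect selection (character vector of effect-matrix
#'   names summed before analysis, e.g. `"MTf"` or `c("MTf", "MTGf")`), or
#'   a list of such selections. Multiple selections share the replicate
#'   model fits -- the expensive part -- so asking for several effect
#'   summaries costs little more than one.
#' @param geometry `"trajectory"` or `"individual"`.
#' @param A components to retain.
#' @param n_boot replicates, default 100.
#' @param level nominal coverage, default 0.95.
#' @param seed master seed.
#' @param random_structure passed to [build_design].
#' @param fast_replicates fit replicates with the relaxed optimiser
#'   tolerance of [fit_univariate] (default TRUE); the reference model
#'   always uses full precision.
#' @return list with `results` (one entry per selection, each holding
#'   `reference`, an `sca_result`, and `ci`, a `bootstrap_result`) and
#'   `fit` (the reference `multivariate_fit`). When a single selection was
#'   given, `reference` and `ci` are also exposed at the top level.
#' @export
bootstrap_pipeline <- function(data, basis, effects = "MTf",
                               geometry = c("trajectory", "individual"),
                               A = 3L, n_boot = 100L, level = 0.95,
                               seed = 1L,
                               random_structure = "mirror_fixed",
                               fast_replicates = TRUE) {
  geometry <- match.arg(geometry)
  selections <- if (is.list(effects)) effects else list(effects)
  tags <- vapply(selections, paste, "", collapse = "+")

  design <- build_design(data, basis, random_structure)
  fit <- fit_all(data, design)
  dec <- decompose_effects(fit)
  refs <- lapply(selections, function(sel)
    analyse_effect(combine_effects(dec, sel), geometry, A = A,
                   dims = fit$dims, labels = dec$labels))
  names(refs) <- tags
  thetas <- lapply(fit$per_variable, `[[`, "theta")

  reps <- bootstrap_subjects(data, n_boot, seed)
  score_list <- lapply(tags, function(...) list())
  loading_list <- lapply(tags, function(...) list())
  names(score_list) <- names(loading_list) <- tags
  n_failed <- 0L
  for (r in seq_along(reps)) {
    aligned <- tryCatch({
      bdata <- reps[[r]]
      bdesign <- build_design(bdata, basis, random_structure)
      bfit <- suppressWarnings(
        fit_all(bdata, bdesign, start_thetas = thetas,
                fast = fast_replicates))
      if (!all(vapply(bfit$per_variable, `[[`, logical(1), "converged")))
        stop("replicate fit did not converge")
      bdec <- decompose_effects(bfit)
      lapply(seq_along(selections), function(s) {
        bM <- combine_effects(bdec, selections[[s]])
        bres <- analyse_effect(bM, geometry, A = refs[[s]]$A,
                               dims = bfit$dims, labels = bdec$labels,
                               cap_A = FALSE)
        procrustes_align(bres$loadings, refs[[s]]$loadings, bres$scores)
      })
    }, error = function(e) NULL)
    if (is.null(aligned)) {
      n_failed <- n_failed + 1L
    } else {
      for (s in seq_along(tags)) {
        score_list[[s]][[length(score_list[[s]]) + 1L]] <-
          aligned[[s]]$scores
        loading_list[[s]][[length(loading_list[[s]]) + 1L]] <-
          aligned[[s]]$loadings
      }
    }
  }
  if (n_failed > n_boot / 2)
    stop("more than half of the bootstrap replicates failed (",
         n_failed, "/", n_boot, "); model is unstable on this data",
         call. = FALSE)

  results <- lapply(seq_along(tags), function(s) {
    ref <- refs[[s]]
    n_ok <- length(score_list[[s]])
    s_arr <- array(unlist(score_list[[s]]),
                   dim = c(nrow(ref$scores), ref$A, n_ok))
    l_arr <- array(unlist(loading_list[[s]]),
                   dim = c(nrow(ref$loadings), ref$A, n_ok))
    ci <- percentile_ci(aperm(s_arr, c(3, 1, 2)),
                        aperm(l_arr, c(3, 1, 2)),
                        level = level, n_failed = n_failed)
    list(reference = ref, ci = ci)
  })
  names(results) <- tags
  out <- list(results = results, fit = fit)
  if (length(results) == 1L) {
    out$reference <- results[[1]]$reference
    out$ci <- results[[1]]$ci
  }
  out
}
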