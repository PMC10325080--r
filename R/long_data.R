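#' Long-format longitudinal dataset
#'
#' A `long_dataset` is a data frame in long format holding one row per
#' (subject, treatment occasion, sample time) with `J` numeric response
#' columns, used throughout the package as the canonical data container.
#' Rows are kept in a fixed canonical order -- subject-major, then
#' treatment, then ascending time -- because every downstream reshape and
#' design-matrix operation indexes rows by that convention.
#'
#' @param data a data.frame containing at least the subject, treatment and
#'   time columns plus one or more numeric response columns.
#' @param subject,treatment,time names of the identifier columns.
#' @param responses character vector of response column names. Defaults to
#'   every numeric column other than `time`.
#' @param lod optional logical matrix (same rows as `data`, one column per
#'   response) flagging below-detection-limit cells, or a character vector
#'   naming logical columns of `data` aligned with `responses`.
#' @return an object of class `long_dataset`: the reordered data.frame with
#'   attributes `subject`, `treatment`, `time`, `responses` and optionally
#'   `lod`.
#' @examples
#' df <- expand.grid(subject = c("s1", "s2"), treatment = c("A", "B"),
#'                   time = 0:3)
#' df$glc <- rnorm(nrow(df), 5)
#' ld <- long_dataset(df, "subject", "treatment", "time")
#' asca_dims(ld)
#' @export
long_dataset <- function(data, subject = "subject", treatment = "treatment",
                         time = "time", responses = NULL, lod = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(subject, treatment, time)) {
    if (!col %in% names(data))
      stop("column '", col, "' not found in data", call. = FALSE)
  }
  if (!is.numeric(data[[time]]))
    stop("time column '", time, "' must be numeric, not ",
         class(data[[time]])[1], call. = FALSE)
  if (is.null(responses)) {
    cand <- setdiff(names(data), c(subject, treatment, time))
    responses <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  if (length(responses) < 1L)
    stop("no numeric response columns found", call. = FALSE)
  for (r in responses) {
    v <- data[[r]]
    if (!is.numeric(v))
      stop("response '", r, "' is not numeric", call. = FALSE)
    if (any(is.infinite(v)))
      stop("response '", r, "' contains non-finite values", call. = FALSE)
  }

  key <- paste(data[[subject]], data[[treatment]], data[[time]], sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (subject, treatment, time) triple: (%s, %s, %s)",
                 d[[subject]], d[[treatment]], d[[time]]), call. = FALSE)
  }

  if (is.character(lod)) {
    stopifnot(length(lod) == length(responses))
    lod <- vapply(lod, function(cn) as.logical(data[[cn]]),
                  logical(nrow(data)))
  }
  if (!is.null(lod)) {
    lod <- as.matrix(lod)
    stopifnot(nrow(lod) == nrow(data), ncol(lod) == length(responses))
    colnames(lod) <- responses
    lod[is.na(lod)] <- FALSE
  }

  sub_f <- factor(data[[subject]], levels = sort(unique(as.character(data[[subject]]))))
  trt_f <- factor(data[[treatment]], levels = sort(unique(as.character(data[[treatment]]))))
  ord <- order(sub_f, trt_f, data[[time]])
  out <- data[ord, c(subject, treatment, time, responses), drop = FALSE]
  names(out)[1:3] <- c("subject", "treatment", "time")
  out$subject <- as.character(out$subject)
  out$treatment <- as.character(out$treatment)
  rownames(out) <- NULL
  if (!is.null(lod)) lod <- lod[ord, , drop = FALSE]

  structure(out,
            responses = responses,
            lod = lod,
            class = c("long_dataset", "data.frame"))
}

#' Dimensions of a long dataset
#'
#' @param data a `long_dataset`.
#' @return a list with elements `I` (subjects), `H` (treatments), `K`
#'   (time points), `J` (responses). For a complete cross-over grid,
#'   `I * H * K` equals the row count.
#' @export
asca_dims <- function(data) {
  stopifnot(inherits(data, "long_dataset"))
  list(I = length(unique(data$subject)),
       H = length(unique(data$treatment)),
       K = length(unique(data$time)),
       J = length(attr(data, "responses")))
}

#' @export
print.long_dataset <- function(x, ...) {
  d <- asca_dims(x)
  cat(sprintf("long_dataset: %d rows, I=%d subjects x H=%d treatments x K=%d times, J=%d responses\n",
              nrow(x), d$I, d$H, d$K, d$J))
  cat("responses:", paste(utils::head(attr(x, "responses"), 8), collapse = ", "),
      if (d$J > 8) "..." else "", "\n")
  invisible(x)
}

#' Check that a dataset covers the full subject x treatment x time grid
#' @param data a `long_dataset`.
#' @return TRUE invisibly; errors if the grid is incomplete.
#' @export
assert_complete_grid <- function(data) {
  d <- asca_dims(data)
  if (nrow(data) != d$I * d$H * d$K)
    stop(sprintf("incomplete design grid: %d rows but I*H*K = %d",
                 nrow(data), d$I * d$H * d$K), call. = FALSE)
  invisible(TRUE)
}

#' Read a long-format CSV into a `long_dataset`
#'
#' Reads a UTF-8 CSV with a header row, maps columns via `columns`, coerces
#' responses to numeric (unparseable cells become missing, with a message
#' reporting the count) and returns the data in canonical row order.
#'
#' @param path CSV file path.
#' @param columns named list/vector with entries `subject`, `treatment`,
#'   `time`, and optionally `responses` (character vector; default: all
#'   remaining columns) and `lod` (names of logical below-LOD flag columns,
#'   aligned with `responses`).
#' @return a [long_dataset].
#' @export
read_long_csv <- function(path, columns = list(subject = "subject",
                                               treatment = "treatment",
                                               time = "time")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (key in c("subject", "treatment", "time")) {
    if (is.null(columns[[key]]))
      stop("column map must name a '", key, "' column", call. = FALSE)
    if (!columns[[key]] %in% names(raw))
      stop("mapped column '", columns[[key]], "' absent from ", path,
           call. = FALSE)
  }
  tcol <- columns[["time"]]
  tval <- suppressWarnings(as.numeric(raw[[tcol]]))
  if (anyNA(tval) && !all(is.na(raw[[tcol]]) == is.na(tval)))
    stop("time column '", tcol, "' does not parse as numeric", call. = FALSE)
  raw[[tcol]] <- tval

  responses <- columns[["responses"]]
  if (is.null(responses))
    responses <- setdiff(names(raw),
                         c(columns[["subject"]], columns[["treatment"]],
                           tcol, columns[["lod"]]))
  n_bad <- 0L
  for (r in responses) {
    v <- suppressWarnings(as.numeric(raw[[r]]))
    n_bad <- n_bad + sum(is.na(v) & !is.na(raw[[r]]) & raw[[r]] != "")
    raw[[r]] <- v
  }
  if (n_bad > 0L)
    message(n_bad, " unparseable response cell(s) set to missing")

  long_dataset(raw, subject = columns[["subject"]],
               treatment = columns[["treatment"]], time = tcol,
               responses = responses, lod = columns[["lod"]])
}

#' Write a `long_dataset` back to CSV
#'
#' @param data a `long_dataset`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_long_csv <- function(data, path) {
  stopifnot(inherits(data, "long_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Blank out below-detection-limit cells
#'
#' Cells flagged as below the limit of detection are set to missing. Rows
#' are never deleted, so the design grid stays rectangular; the per-variable
#' mixed models simply omit missing cells from estimation.
#'
#' @param data a `long_dataset`. If it carries no `lod` attribute the data
#'   is returned unchanged.
#' @return the dataset with flagged cells set to `NA` and the `lod`
#'   attribute dropped. Errors if a response is flagged in every row.
#' @export
drop_below_lod <- function(data) {
  stopifnot(inherits(data, "long_dataset"))
  lod <- attr(data, "lod")
  if (is.null(lod)) return(data)
  responses <- attr(data, "responses")
  counts <- colSums(lod)
  all_gone <- counts == nrow(data)
  if (any(all_gone))
    stop("response '", responses[which(all_gone)[1]],
         "' is below the detection limit in every row", call. = FALSE)
  for (r in responses) data[[r]][lod[, r]] <- NA_real_
  if (sum(counts) > 0)
    message(sum(counts), " below-LOD cell(s) set to missing (",
            paste0(responses[counts > 0], ": ", counts[counts > 0],
                   collapse = ", "), ")")
  attr(data, "lod") <- NULL
  data
}

#' Scale responses by their baseline standard deviation
#'
#' Divides each response column by the sample standard deviation (n-1
#' denominator) of its baseline observations, pooled over subjects and
#' treatment occasions. Responses with a large natural variance at baseline
#' would otherwise dominate the multivariate decomposition; after scaling,
#' the baseline SD of every response is exactly 1. Pooling across treatment
#' arms reflects the working assumption that treatments do not differ
#' before the challenge.
#'
#' @param data a `long_dataset`.
#' @param baseline_time the time value defining baseline (default 0).
#' @return the scaled dataset; the applied divisors are stored in attribute
#'   `baseline_sd`.
#' @export
baseline_sd_scale <- function(data, baseline_time = 0) {
  stopifnot(inherits(data, "long_dataset"))
  base <- data$time == baseline_time
  if (!any(base))
    stop("no observations at baseline time ", baseline_time, call. = FALSE)
  responses <- attr(data, "responses")
  sds <- numeric(length(responses))
  names(sds) <- responses
  for (r in responses) {
    v <- data[[r]][base]
    v <- v[!is.na(v)]
    if (length(v) < 2)
      stop("response '", r, "' has fewer than 2 baseline observations",
           call. = FALSE)
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0)
      stop("baseline SD of response '", r, "' is zero or undefined",
           call. = FALSE)
    sds[r] <- s
    data[[r]] <- data[[r]] / s
  }
  attr(data, "baseline_sd") <- sds
  data
}

#' Extract the response matrix Y (IHK x J) from a long dataset
#' @param data a `long_dataset` in canonical order.
#' @return numeric matrix with one column per response.
#' @export
response_matrix <- function(data) {
  stopifnot(inherits(data, "long_dataset"))
  as.matrix(as.data.frame(data)[, attr(data, "responses"), drop = FALSE])
}
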