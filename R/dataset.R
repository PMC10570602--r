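#' Multivariate time-series dataset
#'
#' Container for a panel of `N` subjects observed over `Q` ordered time steps
#' (waves) on `M` variables, with an observation mask and optional binary
#' labels. This is the `(N, Q, M)` tensor every other function in the package
#' consumes.
#'
#' @param values numeric array of shape `(N, Q, M)`. `NA` entries are allowed
#'   and are recorded as unobserved in the mask.
#' @param mask logical array of the same shape, `TRUE` = observed. Defaults to
#'   `!is.na(values)`.
#' @param labels optional integer vector of length `N` with values in `{0,1}`.
#' @param feature_names character vector of length `M`, unique. Defaults to
#'   `"V1"..."VM"` or the array's dimnames.
#' @param time_labels vector of length `Q`, strictly increasing when numeric.
#' @return an object of class `time_series_dataset` with fields `values`,
#'   `mask`, `labels`, `feature_names`, `time_labels`.
#' @examples
#' x <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
#' ds <- time_series_dataset(x, labels = c(0L, 1L))
#' dim(ds$values)
#' @export
time_series_dataset <- function(values, mask = NULL, labels = NULL,
                                feature_names = NULL, time_labels = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array of shape (N, Q, M)")
  storage.mode(values) <- "double"
  d <- dim(values)
  if (is.null(mask)) mask <- !is.na(values)
  if (is.null(feature_names)) {
    feature_names <- dimnames(values)[[3]]
    if (is.null(feature_names)) feature_names <- paste0("V", seq_len(d[3]))
  }
  if (is.null(time_labels)) {
    time_labels <- dimnames(values)[[2]]
    if (is.null(time_labels)) time_labels <- seq_len(d[2])
  }
  ds <- structure(
    list(values = values, mask = mask, labels = labels,
         feature_names = as.character(feature_names),
         time_labels = time_labels),
    class = "time_series_dataset")
  validate_time_series_dataset(ds)
}

#' Validate a time_series_dataset
#'
#' Checks the container invariants: matching shapes, finite observed values,
#' unique feature names, binary labels, ordered time labels. Called by every
#' constructor/reader; exported so property tests can use it directly.
#'
#' @param ds a `time_series_dataset`.
#' @return `ds`, invisibly unchanged, or an error.
#' @export
validate_time_series_dataset <- function(ds) {
  d <- dim(ds$values)
  stopifnot(length(d) == 3L)
  if (any(d < 1L)) stop("N, Q and M must all be >= 1")
  if (!is.logical(ds$mask) || !identical(dim(ds$mask), d))
    stop("`mask` must be a logical array with the same shape as `values`")
  if (anyNA(ds$mask)) stop("`mask` must not contain NA")
  obs <- ds$values[ds$mask]
  if (length(obs) && !all(is.finite(obs)))
    stop("all observed (mask TRUE) values must be finite")
  if (length(ds$feature_names) != d[3] || anyDuplicated(ds$feature_names))
    stop("`feature_names` must be ", d[3], " unique names")
  if (length(ds$time_labels) != d[2])
    stop("`time_labels` must have length Q = ", d[2])
  if (is.numeric(ds$time_labels) && is.unsorted(ds$time_labels, strictly = TRUE))
    stop("numeric `time_labels` must be strictly increasing")
  if (!is.null(ds$labels)) {
    if (length(ds$labels) != d[1])
      stop("`labels` must have length N = ", d[1])
    if (!all(ds$labels %in% c(0L, 1L)))
      stop("`labels` must be 0/1")
  }
  ds
}

#' @export
print.time_series_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "time_series_dataset: %d subjects x %d time steps x %d variables\n",
    d[1], d[2], d[3]))
  cat(sprintf("  observed cells: %.1f%%", 100 * mean(x$mask)))
  if (!is.null(x$labels))
    cat(sprintf("; positive labels: %d/%d", sum(x$labels == 1L), d[1]))
  cat("\n")
  invisible(x)
}

#' @export
dim.time_series_dataset <- function(x) dim(x$values)

n_subjects <- function(ds) dim(ds$values)[1]
n_waves <- function(ds) dim(ds$values)[2]
n_features <- function(ds) dim(ds$values)[3]

# subject-level subsetting, used by the splitter
subset_subjects <- function(ds, idx) {
  time_series_dataset(
    ds$values[idx, , , drop = FALSE],
    mask = ds$mask[idx, , , drop = FALSE],
    labels = if (!is.null(ds$labels)) ds$labels[idx],
    feature_names = ds$feature_names,
    time_labels = ds$time_labels)
}

# evaluate and restore RNG state; all in-package randomness goes through this
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
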