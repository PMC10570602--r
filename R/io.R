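#' Read a long-format panel CSV
#'
#' One row per subject-wave. Subjects are ordered by first appearance, time
#' steps ascending by the time value; a subject's absent waves become
#' mask-false cells. The label, when a label column is given, is taken from
#' the last wave where it is present and must agree across waves.
#'
#' @param path CSV file with a header.
#' @param id_column,time_column column names identifying subject and wave.
#' @param feature_columns character vector of feature columns; default all
#'   columns except id, time and label.
#' @param label_column optional name of the 0/1 label column.
#' @return a [time_series_dataset()].
#' @export
read_long_csv <- function(path, id_column = "id", time_column = "time",
                          feature_columns = NULL, label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, na.strings = c("NA", ""))
  for (col in c(id_column, time_column, label_column))
    if (!col %in% names(dt)) stop("column not found in ", path, ": ", col)
  if (is.null(feature_columns))
    feature_columns <- setdiff(names(dt), c(id_column, time_column, label_column))
  missing_feat <- setdiff(feature_columns, names(dt))
  if (length(missing_feat))
    stop("feature columns not found: ", paste(missing_feat, collapse = ", "))

  ids <- dt[[id_column]]
  times <- dt[[time_column]]
  dup <- duplicated(data.frame(ids, times))
  if (any(dup)) {
    k <- which(dup)[1]
    stop(sprintf("duplicate (id, time) pair: (%s, %s)", ids[k], times[k]))
  }
  uid <- unique(ids)                 # first-appearance order
  utime <- sort(unique(times))       # ascending waves
  N <- length(uid); Q <- length(utime); M <- length(feature_columns)

  values <- array(NA_real_, dim = c(N, Q, M),
                  dimnames = list(NULL, as.character(utime), feature_columns))
  ri <- match(ids, uid); ci <- match(times, utime)
  for (m in seq_len(M)) {
    col <- as.numeric(dt[[feature_columns[m]]])
    values[cbind(ri, ci, m)] <- col
  }

  labels <- NULL
  if (!is.null(label_column)) {
    lab <- as.integer(dt[[label_column]])
    labels <- rep(NA_integer_, N)
    ord <- order(ci)                 # so later waves overwrite earlier ones
    for (k in ord) if (!is.na(lab[k])) {
      if (!is.na(labels[ri[k]]) && labels[ri[k]] != lab[k])
        stop("conflicting labels for subject ", uid[ri[k]])
      labels[ri[k]] <- lab[k]
    }
    if (anyNA(labels))
      stop("no label observed for subject(s): ",
           paste(uid[is.na(labels)], collapse = ", "))
  }
  time_series_dataset(values, labels = labels,
                      feature_names = feature_columns, time_labels = utime)
}

#' Read a wide-format panel CSV
#'
#' One row per subject; feature columns named `<feature>__<time_label>`, plus
#' an id column and optionally a label column.
#'
#' @inheritParams read_long_csv
#' @return a [time_series_dataset()].
#' @export
read_wide_csv <- function(path, id_column = "id", label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, na.strings = c("NA", ""))
  value_cols <- setdiff(names(dt), c(id_column, label_column))
  parts <- regmatches(value_cols, regexpr("__(?=[^_]+$)", value_cols, perl = TRUE),
                      invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("wide columns must be named <feature>__<time>: ", value_cols[bad][1])
  feats <- vapply(parts, `[`, "", 1L)
  times <- vapply(parts, `[`, "", 2L)
  ufeat <- unique(feats)
  tnum <- suppressWarnings(as.numeric(unique(times)))
  utime <- if (!anyNA(tnum)) sort(unique(tnum)) else unique(times)
  N <- nrow(dt); Q <- length(utime); M <- length(ufeat)
  values <- array(NA_real_, dim = c(N, Q, M))
  for (k in seq_along(value_cols)) {
    q <- match(if (!anyNA(tnum)) as.numeric(times[k]) else times[k], utime)
    m <- match(feats[k], ufeat)
    values[, q, m] <- as.numeric(dt[[value_cols[k]]])
  }
  labels <- if (!is.null(label_column)) as.integer(dt[[label_column]])
  time_series_dataset(values, labels = labels, feature_names = ufeat,
                      time_labels = utime)
}

#' Write a dataset as long-format CSV
#'
#' Inverse of [read_long_csv()]; mask-false cells are written as `NA`.
#'
#' @param ds a `time_series_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path) {
  d <- dim(ds$values)
  rows <- expand.grid(time = seq_len(d[2]), id = seq_len(d[1]))[, c("id", "time")]
  vals <- matrix(NA_real_, nrow(rows), d[3])
  for (m in seq_len(d[3])) {
    x <- ds$values[, , m]
    x[!ds$mask[, , m]] <- NA_real_
    vals[, m] <- as.vector(t(x))
  }
  colnames(vals) <- ds$feature_names
  out <- data.frame(id = rows$id,
                    time = ds$time_labels[rows$time], vals,
                    check.names = FALSE)
  if (!is.null(ds$labels)) out$label <- ds$labels[rows$id]
  data.table::fwrite(out, path, na = "NA")
  invisible(path)
}

#' Read a sktime/UEA-style multivariate `.ts` file
#'
#' Supports the equal-length dialect: `@`-prefixed header tags, then one line
#' per case, with the per-dimension series separated by `:` and the class
#' label last. Two-class problems are mapped to labels in `{0,1}` (order of
#' `@classLabel` when given, else sorted); other problems keep 0-based
#' integer codes.
#'
#' @param path `.ts` file.
#' @return a [time_series_dataset()] of shape `(N, Q, M)` where `Q` is the
#'   series length and `M` the number of dimensions.
#' @export
read_ts_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  known <- c("@problemname", "@timestamps", "@missing", "@univariate",
             "@dimension", "@equallength", "@serieslength", "@targetlabel",
             "@classlabel", "@data")
  class_levels <- NULL
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "@")) next
    tag <- tolower(strsplit(ln, "\\s+")[[1]][1])
    if (!tag %in% known) {
      warning("unknown header tag skipped: ", tag)
      next
    }
    if (tag == "@classlabel") {
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) >= 3 && tolower(toks[2]) == "true")
        class_levels <- toks[-(1:2)]
    }
    if (tag == "@data") { data_start <- i + 1L; break }
  }
  if (is.na(data_start)) stop("no @data section in ", path)
  body <- lines[seq(data_start, length(lines))]
  if (!length(body)) stop("empty @data section in ", path)

  parsed <- lapply(body, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed .ts case line: ", ln)
    label <- trimws(parts[length(parts)])
    dims <- lapply(parts[-length(parts)], function(p)
      as.numeric(strsplit(trimws(p), ",", fixed = TRUE)[[1]]))
    list(label = label, dims = dims)
  })
  M <- length(parsed[[1]]$dims)
  lens <- unlist(lapply(parsed, function(p) vapply(p$dims, length, 1L)))
  if (length(unique(lens)) != 1L)
    stop("ragged series lengths; unequal-length series are unsupported")
  Q <- lens[1]
  N <- length(parsed)
  values <- array(NA_real_, dim = c(N, Q, M))
  for (i in seq_len(N))
    for (m in seq_len(M)) values[i, , m] <- parsed[[i]]$dims[[m]]

  raw <- vapply(parsed, `[[`, "", "label")
  if (is.null(class_levels)) class_levels <- sort(unique(raw))
  codes <- match(raw, class_levels) - 1L
  if (anyNA(codes)) stop("class label outside @classLabel set: ",
                         raw[is.na(codes)][1])
  labels <- if (length(class_levels) == 2L) codes else NULL
  ds <- time_series_dataset(values, labels = labels)
  if (is.null(labels)) attr(ds, "class_codes") <- codes
  ds
}

#' Write a dataset to `.ts` format
#'
#' @param ds a fully observed, labeled `time_series_dataset`.
#' @param path output file.
#' @param problem_name value for the `@problemName` tag.
#' @return `path`, invisibly.
#' @export
write_ts_file <- function(ds, path, problem_name = "dataset") {
  if (!all(ds$mask)) stop("write_ts_file requires a fully observed dataset")
  if (is.null(ds$labels)) stop("write_ts_file requires labels")
  d <- dim(ds$values)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("@problemName", problem_name),
    "@timeStamps false",
    "@missing false",
    paste("@univariate", if (d[3] == 1L) "true" else "false"),
    "@equalLength true",
    paste("@seriesLength", d[2]),
    "@classLabel true 0 1",
    "@data"), con)
  for (i in seq_len(d[1])) {
    dims <- vapply(seq_len(d[3]), function(m)
      paste(format(ds$values[i, , m], digits = 17, trim = TRUE,
                   scientific = FALSE), collapse = ","), "")
    writeLines(paste0(paste(dims, collapse = ":"), ":", ds$labels[i]), con)
  }
  invisible(path)
}
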