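#' Score CESD-10 responses
#'
#' The 10-item Center for Epidemiologic Studies Depression short scale. Each
#' item is answered on a 4-option frequency scale (1 = "Rarely or none of the
#' time" up to 4 = "Most or all of the time"). Items 5 ("I felt hopeful about
#' the future") and 8 ("I was happy") are positively worded and reverse
#' scored: they contribute `4 - option`; the remaining eight items contribute
#' `option - 1`. The total ranges 0-30.
#'
#' @param responses an integer vector of length 10, or an `n x 10` matrix /
#'   data frame (columns `cesd_q1`..`cesd_q10` order), with entries in
#'   `{1, 2, 3, 4}`. Missing responses are an error: the scale is not
#'   prorated, since partial totals would silently shift the diagnostic
#'   threshold.
#' @return integer score(s) in `[0, 30]`.
#' @examples
#' score_cesd(rep(1L, 10))          # minimum frequencies -> 6 (reverse items)
#' score_cesd(c(4,4,4,4,1,4,4,1,4,4))  # maximum possible total, 30
#' @export
score_cesd <- function(responses) {
  x <- if (is.data.frame(responses)) as.matrix(responses) else responses
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 10L) stop("CESD-10 requires exactly 10 item responses")
  if (anyNA(x) || !all(x %in% 1:4))
    stop("CESD-10 responses must all be in {1, 2, 3, 4} with no missing items")
  positive <- c(5L, 8L)
  item_scores <- x - 1L
  item_scores[, positive] <- 4L - x[, positive]
  out <- as.integer(rowSums(item_scores))
  if (length(out) == 1L && is.null(dim(responses))) out[[1]] else out
}

#' Binary depression label from a CESD-10 score
#'
#' Scores strictly above 10 define the depressive group; scores less than or
#' equal to 10 the normal group.
#'
#' @param score integer vector of CESD-10 totals in `[0, 30]`.
#' @return integer vector of labels in `{0, 1}`.
#' @examples
#' label_depression(c(10, 11))  # 0 1
#' @export
label_depression <- function(score) {
  if (anyNA(score) || any(score < 0 | score > 30))
    stop("CESD-10 scores must lie in [0, 30]")
  as.integer(score > 10)
}

#' Score a CSV of CESD-10 responses
#'
#' Reads columns `cesd_q1`..`cesd_q10` (option indices 1-4), appends `score`
#' and `label` columns, and optionally writes the result.
#'
#' @param path input CSV.
#' @param out optional output CSV path.
#' @return the augmented data frame, invisibly when `out` is given.
#' @export
score_cesd_file <- function(path, out = NULL) {
  dt <- data.table::fread(path)
  cols <- paste0("cesd_q", 1:10)
  if (!all(cols %in% names(dt)))
    stop("input must contain columns ", paste(cols, collapse = ", "))
  sc <- score_cesd(as.matrix(dt[, cols, with = FALSE]))
  dt$score <- sc
  dt$label <- label_depression(sc)
  if (!is.null(out)) {
    data.table::fwrite(dt, out)
    return(invisible(as.data.frame(dt)))
  }
  as.data.frame(dt)
}
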