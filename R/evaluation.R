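#' Build a 2 x 2 confusion table
#'
#' Cross-tabulates actual against predicted class codes (1 = target weed,
#' 2 = other vegetation). Code 0 (nodata) must be excluded upstream.
#'
#' @param actual,predicted integer vectors of equal length with codes in
#'   \{1, 2\}.
#' @return a [ConfusionTable-class] with rows = actual, columns = predicted.
#' @export
confusionTable <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual (", length(actual), ") and predicted (", length(predicted),
         ") lengths differ")
  }
  if (!all(actual %in% c(1L, 2L)) || !all(predicted %in% c(1L, 2L))) {
    stop("class codes must be 1 (target) or 2 (other); exclude nodata upstream")
  }
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(actual = c("target", "other"),
                                   predicted = c("target", "other")))
  for (a in 1:2) for (p in 1:2) {
    counts[a, p] <- sum(actual == a & predicted == p)
  }
  new("ConfusionTable", counts = counts)
}

#' Accuracy metrics from a confusion table
#'
#' The standard remote-sensing accuracy-assessment arithmetic, as
#' percentages:
#' \itemize{
#'   \item overall accuracy: `100 * trace / N`;
#'   \item producer's accuracy of class c: correct predictions of c over
#'     the *actual* total of c (its complement is the omission error);
#'   \item user's accuracy of class c: correct predictions of c over all
#'     *predictions* of c;
#'   \item omission error: `100 - producer's`;
#'   \item commission error of class c: pixels of the opposite class
#'     wrongly assigned to c, over the actual total of the opposite class
#'     (the "overestimation" rate of foreign pixels).
#' }
#' Metrics with a zero denominator are reported as `NA` (undefined), never
#' as 0. Values are kept at full precision; round only for presentation
#' (see [formatMetrics()]).
#'
#' @param table a [ConfusionTable-class].
#' @return list with `overall`, and per-class named vectors `users`,
#'   `producers`, `omission`, `commission`.
#' @examples
#' ct <- new("ConfusionTable",
#'           counts = matrix(c(416L, 9L, 25L, 410L), 2, 2))
#' accuracyMetrics(ct)$overall  # 96.05
#' @export
accuracyMetrics <- function(table) {
  stopifnot(is(table, "ConfusionTable"))
  ct <- table@counts
  n <- sum(ct)
  rowTot <- rowSums(ct)
  colTot <- colSums(ct)
  safe <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  producers <- c(target = safe(ct[1L, 1L], rowTot[[1L]]),
                 other  = safe(ct[2L, 2L], rowTot[[2L]]))
  users <- c(target = safe(ct[1L, 1L], colTot[[1L]]),
             other  = safe(ct[2L, 2L], colTot[[2L]]))
  commission <- c(target = safe(colTot[[1L]] - ct[1L, 1L], rowTot[[2L]]),
                  other  = safe(colTot[[2L]] - ct[2L, 2L], rowTot[[1L]]))
  list(overall = safe(sum(diag(ct)), n),
       users = users, producers = producers,
       omission = 100 - producers, commission = commission)
}

#' Round metrics for presentation
#'
#' Rounds every metric half-up to 2 decimals, matching how contingency-table
#' accuracies are conventionally printed.
#'
#' @param metrics output of [accuracyMetrics()].
#' @return the same structure, rounded.
#' @export
formatMetrics <- function(metrics) {
  rapply(metrics, function(x) roundHalfUp(x, 2L), how = "replace")
}

setMethod("show", "ConfusionTable", function(object) {
  cat("ConfusionTable (rows actual, columns predicted)\n")
  print(object@counts)
  m <- formatMetrics(accuracyMetrics(object))
  cat("overall accuracy:", m$overall, "%\n")
})
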