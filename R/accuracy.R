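#' A 2 x 2 classification confusion matrix
#'
#' Rows are the mapped class, columns the reference class, in the order
#' (non-rapeseed `NOR`, rapeseed `OR`) — the orientation in which user
#' accuracy (UA) is row-wise and producer accuracy (PA) column-wise.
#'
#' @param counts 2 x 2 matrix (or something coercible) of non-negative
#'   integer pixel counts.
#' @param classes Length-2 character vector of class labels.
#' @return A `confusion_matrix2` object.
#' @examples
#' confusion_matrix2(rbind(c(27418, 2226), c(4163, 21249)))
#' @export
confusion_matrix2 <- function(counts, classes = c("NOR", "OR")) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("`counts` must be 2 x 2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("total count must be positive", call. = FALSE)
  dimnames(counts) <- list(mapped = classes, reference = classes)
  structure(counts, class = c("confusion_matrix2", "matrix"))
}

#' Accuracy metrics from a 2 x 2 confusion matrix
#'
#' Overall accuracy `OA = trace/total`; user accuracy per class
#' `UA_c = diag_c / rowsum_c`; producer accuracy per class
#' `PA_c = diag_c / colsum_c`; Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with `p_e = sum_c rowsum_c * colsum_c / total^2`.
#' Accuracies are reported in percent at full precision (round only for
#' display); a zero row or column sum leaves the affected UA/PA `NA` while
#' the rest are still computed.
#'
#' @param m A [confusion_matrix2()] (or a raw 2 x 2 count matrix).
#' @return A `confusion_metrics` list with elements `oa`, `ua`, `pa`
#'   (percent), `kappa`, `n` and the matrix itself.
#' @examples
#' confusion_metrics(confusion_matrix2(rbind(c(27418, 2226), c(4163, 21249))))
#' @export
confusion_metrics <- function(m) {
  if (!inherits(m, "confusion_matrix2")) m <- confusion_matrix2(m)
  total <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  p_o <- sum(diag(m)) / total
  p_e <- sum(rs * cs) / total^2
  safe <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  structure(
    list(
      oa = 100 * p_o,
      ua = 100 * safe(diag(m), rs),
      pa = 100 * safe(diag(m), cs),
      kappa = if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1,
      n = total,
      matrix = m
    ),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("Confusion-matrix accuracy (n =", format(x$n, big.mark = ","), "pixels)\n")
  cat(sprintf("  OA: %.2f%%   kappa: %.2f\n", x$oa, x$kappa))
  for (cl in names(x$ua)) {
    cat(sprintf("  %s: UA %.2f%%  PA %.2f%%\n", cl, x$ua[cl], x$pa[cl]))
  }
  invisible(x)
}

#' @rdname confusion_metrics
#' @param x A `confusion_metrics` object.
#' @param ... Ignored.
#' @return `tidy()` returns one row per class (UA/PA); `glance()` a one-row
#'   tibble with OA, kappa and n.
#' @export
tidy.confusion_metrics <- function(x, ...) {
  tibble::tibble(
    class = names(x$ua),
    user_accuracy = as.numeric(x$ua),
    producer_accuracy = as.numeric(x$pa)
  )
}

#' @rdname confusion_metrics
#' @export
glance.confusion_metrics <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$oa, kappa = x$kappa, n = x$n)
}

#' Read a confusion matrix from CSV or JSON
#'
#' CSV layout: a header row and a label column, counts in the 2 x 2 body
#' (mapped classes on rows). JSON layout: `{"classes": [...], "counts":
#' [[...],[...]]}`.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A [confusion_matrix2()].
#' @export
read_confusion <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    counts <- if (is.matrix(j$counts)) j$counts else
      do.call(rbind, as.list(j$counts))
    classes <- if (!is.null(j$classes)) j$classes else c("NOR", "OR")
  } else {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    counts <- as.matrix(df[1:2, 1:2])
    classes <- rownames(df)[1:2]
  }
  confusion_matrix2(counts, classes)
}
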