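.as_binary_array <- function(x, what = "input") {
  if (inherits(x, "volume")) x <- x$data
  if (!is.numeric(x)) stop(what, " must be numeric")
  if (!all(x %in% c(0, 1))) stop(what, " must be binary {0,1}")
  x
}

#' Dice similarity coefficient
#'
#' `DSC = 2|A∩B| / (|A| + |B|)` between two equally shaped binary arrays or
#' mask volumes. Symmetric in its arguments. When both masks are empty the
#' coefficient is defined as 1 (perfect agreement on "nothing there").
#'
#' @param a,b Binary arrays or mask [volume]s of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- .as_binary_array(a, "a")
  b <- .as_binary_array(b, "b")
  da <- if (is.null(dim(a))) length(a) else dim(a)
  db <- if (is.null(dim(b))) length(b) else dim(b)
  if (!identical(as.integer(da), as.integer(db))) stop("shape mismatch between a and b")
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Soft Dice loss
#'
#' `L = 1 - (2 Σ y ŷ + ε) / (Σ y + Σ ŷ + ε)`, the training objective: the
#' Dice coefficient relaxed to probabilities and turned into a loss. The
#' additive smoothing `ε` (default `1e-6`) guards the empty-mask 0/0 case
#' and stabilizes gradients.
#'
#' @param y Binary target array.
#' @param y_hat Probability array in `[0, 1]`, same shape as `y`.
#' @param eps Smoothing constant.
#' @return Loss value in `[0, 1]`.
#' @export
dice_loss <- function(y, y_hat, eps = 1e-6) {
  y <- .as_binary_array(y, "y")
  if (inherits(y_hat, "volume")) y_hat <- y_hat$data
  if (length(y) != length(y_hat)) stop("shape mismatch between y and y_hat")
  if (any(y_hat < -1e-9 | y_hat > 1 + 1e-9)) stop("y_hat must lie in [0,1]")
  1 - (2 * sum(y * y_hat) + eps) / (sum(y) + sum(y_hat) + eps)
}

#' Summary statistics over per-case DSC scores
#'
#' @param scores Nonempty numeric vector of DSC fractions in `[0, 1]`.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return A `score_summary`: mean, std, max, min, n_cases.
#' @export
summarize_scores <- function(scores, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(scores) == 0) stop("empty score list")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  n <- length(scores)
  m <- mean(scores)
  s <- if (n == 1) 0 else {
    v <- sum((scores - m)^2) / if (sd_type == "population") n else (n - 1)
    sqrt(v)
  }
  structure(list(mean = m, std = s, max = max(scores), min = min(scores),
                 n_cases = n),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("DSC over %d cases: mean %.4f +/- %.4f (min %.4f, max %.4f)\n",
              x$n_cases, x$mean, x$std, x$min, x$max))
  invisible(x)
}

#' DSC distribution histogram
#'
#' Bins scores into the six-bin structure used for slice-level analysis:
#' `[0, 0.5]` (closed), then half-open-left bins `(0.5, 0.6]`, `(0.6, 0.7]`,
#' `(0.7, 0.8]`, `(0.8, 0.9]`, `(0.9, 1]`. Fractions are percentages summing
#' to 100.
#'
#' @param scores Numeric vector of DSC fractions in `[0, 1]`.
#' @return A `dsc_histogram`: `bin_edges` and per-bin `fractions` (percent).
#' @export
dsc_histogram <- function(scores) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  edges <- c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
  # right-closed bins; values <= 0.5 (including 0) land in the first bin
  idx <- findInterval(scores, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L  # score exactly 0
  counts <- tabulate(idx, nbins = 6L)
  labels <- c("[0, 0.5]", "(0.5, 0.6]", "(0.6, 0.7]", "(0.7, 0.8]",
              "(0.8, 0.9]", "(0.9, 1]")
  structure(list(bin_edges = edges,
                 fractions = stats::setNames(100 * counts / length(scores), labels)),
            class = "dsc_histogram")
}

#' @export
print.dsc_histogram <- function(x, ...) {
  for (i in seq_along(x$fractions)) {
    cat(sprintf("DSC %-10s %6.2f%%\n", names(x$fractions)[i], x$fractions[i]))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes a per-case CSV (`case`, `dsc`), a JSON `score_summary`, and a JSON
#' DSC histogram into `dir`.
#'
#' @param scores Named or unnamed numeric vector of per-case DSC values.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_evaluation <- function(scores, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cases <- if (is.null(names(scores))) paste0("case_", seq_along(scores)) else names(scores)
  csv <- file.path(dir, "per_case_dsc.csv")
  utils::write.csv(data.frame(case = cases, dsc = as.numeric(scores)),
                   csv, row.names = FALSE)
  summ <- summarize_scores(as.numeric(scores))
  sj <- file.path(dir, "summary.json")
  jsonlite::write_json(unclass(summ), sj, auto_unbox = TRUE, digits = NA)
  hist <- dsc_histogram(as.numeric(scores))
  hj <- file.path(dir, "histogram.json")
  jsonlite::write_json(list(bin_edges = hist$bin_edges,
                            fractions = as.list(hist$fractions)),
                       hj, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, sj, hj))
}
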